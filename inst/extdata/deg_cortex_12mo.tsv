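gene	ratio	tissue	age_months
Ihpk1	-1.64	cortex	12
Vps13c	-1.65	cortex	12
Mast2	-1.66	cortex	12
Ngrn	-1.66	cortex	12
Def8	-1.69	cortex	12
Phb	-1.71	cortex	12
C1qb	-1.71	cortex	12
Kcns2	-1.71	cortex	12
Sec23b	-1.73	cortex	12
Acrbp	-1.74	cortex	12
Rcn2	-1.75	cortex	12
Sympk	-1.76	cortex	12
Kdelr1	-1.77	cortex	12
Ankzf1	-1.79	cortex	12
Rock1	-1.81	cortex	12
Prr6	-1.81	cortex	12
Fhit	-1.83	cortex	12
Syde1	-1.86	cortex	12
Dusp12	-1.88	cortex	12
Oxr1	-1.89	cortex	12
Nsf	-1.92	cortex	12
Samm50	-1.93	cortex	12
Trim3	-1.96	cortex	12
Amfr	-1.97	cortex	12
Ttc3	-1.98	cortex	12
Kcnh6	-2.03	cortex	12
Uqcr	-2.08	cortex	12
NRXN1	-2.10	cortex	12
Gm11502	-2.11	cortex	12
cox2	-2.17	cortex	12
Ticam2	-2.19	cortex	12
Tmem186	-2.29	cortex	12
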
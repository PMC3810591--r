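gene	ratio	tissue	age_months
Amfr	1.98	hippocampus	2
Fhit	-1.62	hippocampus	2
Ercc5	-1.63	hippocampus	2
Mast2	-1.66	hippocampus	2
Dip3b	-1.68	hippocampus	2
KDELR1	-1.68	hippocampus	2
Syde1	-1.68	hippocampus	2
Ankzf1	-1.71	hippocampus	2
STUB1	-1.72	hippocampus	2
Kcns2	-1.74	hippocampus	2
Strn4	-1.75	hippocampus	2
Thyn1	-1.76	hippocampus	2
Def8	-1.81	hippocampus	2
Rcn2	-1.81	hippocampus	2
C1qb	-1.82	hippocampus	2
Prr6	-1.84	hippocampus	2
Rab26	-1.84	hippocampus	2
Sec23b	-1.86	hippocampus	2
MTCO1	-1.87	hippocampus	2
Ranbp5	-1.87	hippocampus	2
Snx27	-1.87	hippocampus	2
Sympk	-1.88	hippocampus	2
Mink1	-1.88	hippocampus	2
Trim3	-1.88	hippocampus	2
Dnahc8	-1.93	hippocampus	2
Dusp12	-1.99	hippocampus	2
Vps13c	-2.01	hippocampus	2
Ticam2	-2.01	hippocampus	2
B3gat1	-2.06	hippocampus	2
NSF	-2.10	hippocampus	2
Acrbp	-2.13	hippocampus	2
Ihpk1	-2.15	hippocampus	2
Samm50	-2.15	hippocampus	2
Tmem186	-2.19	hippocampus	2
Olfr272	-2.21	hippocampus	2
Gm11502	-2.23	hippocampus	2
Kcnh6	-2.25	hippocampus	2
Cpsf3l	-2.25	hippocampus	2
Ttc3	-2.36	hippocampus	2
Uqcr	-2.50	hippocampus	2
Ddx3x	-2.53	hippocampus	2
Oxr1	-2.58	hippocampus	2
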
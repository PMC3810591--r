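gene	ratio	tissue	age_months
pol	2.61	cortex	6
Uqcr	1.97	cortex	6
Tmem186	1.93	cortex	6
Ticam2	1.92	cortex	6
cox2	1.87	cortex	6
Gm11502	1.73	cortex	6
C1qb	1.72	cortex	6
Rab26	1.71	cortex	6
Clstn1	1.68	cortex	6
Dusp12	1.68	cortex	6
Trim3	1.67	cortex	6
Def8	1.66	cortex	6
Ihpk1	1.65	cortex	6
Ttc3	1.61	cortex	6
Vps13c	1.60	cortex	6
Slc17a7	-2.13	cortex	6
Rn18s	-2.21	cortex	6
Rps6ka1	-2.27	cortex	6
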
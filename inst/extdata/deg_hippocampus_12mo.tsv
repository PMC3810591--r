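gene	ratio	tissue	age_months
Dnchc1	8.51	hippocampus	12
ARNT2	3.24	hippocampus	12
Rps21	2.97	hippocampus	12
Rcn 2	2.81	hippocampus	12
Tspan2	2.57	hippocampus	12
UQCRFS1	2.32	hippocampus	12
MTCO1	2.28	hippocampus	12
Cstn1	2.26	hippocampus	12
Raf1	2.22	hippocampus	12
Kinectin	2.21	hippocampus	12
ZNF 238	2.14	hippocampus	12
Epha4	2.12	hippocampus	12
Kcnh6	2.12	hippocampus	12
Map3k3	2.12	hippocampus	12
NF-L	2.11	hippocampus	12
ADRBK1	2.09	hippocampus	12
Eph B6	2.06	hippocampus	12
Fin14	1.97	hippocampus	12
Ticam2	1.96	hippocampus	12
Uqcr	1.94	hippocampus	12
KDELR1	1.92	hippocampus	12
Ntrk2	1.92	hippocampus	12
Snx27	1.87	hippocampus	12
Tmem186	1.85	hippocampus	12
Gm11502	1.84	hippocampus	12
Rpl26	1.84	hippocampus	12
Mast2	1.82	hippocampus	12
MTCO3	1.75	hippocampus	12
Kpnb3	1.72	hippocampus	12
Rock1	1.71	hippocampus	12
Olfr273	1.70	hippocampus	12
Thyn1	1.69	hippocampus	12
Vps13c	1.52	hippocampus	12
Ager	-1.59	hippocampus	12
ZNF133	-1.64	hippocampus	12
GANP	-1.66	hippocampus	12
Cdkn2a	-1.68	hippocampus	12
Olfr272	-1.69	hippocampus	12
cox2	-1.72	hippocampus	12
Bbox1	-1.73	hippocampus	12
Fyco1	-1.80	hippocampus	12
DUSP12	-1.84	hippocampus	12
Ankzf1	-1.85	hippocampus	12
NSF	-1.87	hippocampus	12
RAB26	-1.91	hippocampus	12
Ttc3	-1.91	hippocampus	12
Map4k6-pending	-1.96	hippocampus	12
Cacng4	-2.00	hippocampus	12
Mapt	-2.01	hippocampus	12
Fhit	-2.03	hippocampus	12
Strn4	-2.07	hippocampus	12
Rps19bp1	-2.09	hippocampus	12
NRXN1	-2.17	hippocampus	12
RNase H	-2.74	hippocampus	12
STUB1	-3.14	hippocampus	12
Sympk	-3.45	hippocampus	12
CAMK2α	-24.51	hippocampus	12
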
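gene	ratio	tissue	age_months
Penk1	2.70	hippocampus	6
Uqcr	1.94	hippocampus	6
Slc17a7	1.85	hippocampus	6
Ssu72	1.82	hippocampus	6
Prr6	1.79	hippocampus	6
Tmem186	1.67	hippocampus	6
MTCO1	1.67	hippocampus	6
Ankzf1	1.62	hippocampus	6
DUSP12	1.62	hippocampus	6
Rps6ka1	-1.60	hippocampus	6
cox2	-1.72	hippocampus	6
Ttc3	-2.36	hippocampus	6
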
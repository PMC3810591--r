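mirna	n_targets_in_bigraph	p_value
miR-20a	9	8.16E-09
miR-17	10	1.30E-07
miR-34a	9	2.78E-07
miR-155	14	2.16E-07
miR-18a	5	4.04E-06
miR-22	5	6.18E-06
miR-26a	6	9.29E-06
miR-101	5	3.30E-05
miR-106b	5	3.30E-05
miR-125b	8	8.37E-05
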
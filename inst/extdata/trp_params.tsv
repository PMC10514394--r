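reaction_id	dG0_kJ_mol	dG0_sd	kcat_per_MW_h_per_kDa	genes
TRPS1	-30.5	6.2	145.44	b1260 and b1261
TRPS2	-49.7	2.2	/	b1260 and b1261
TRPS3	/	/	/	b1260 and b1261
TRPAS2_reverse	-21.1	1.1	/	b3708
MTRPOXN	-44.6	13.7	/	b1059
ACONT	8.3	0.6	3540	b0118 and b1276
ACONT_r	-8.3	0.6	3540	b0118 and b1276
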
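family	genome	unit	gene	position
ogm	gm1	ogm_gm1_m1	a2	1
ogm	gm1	ogm_gm1_m1	a4	2
ogm	gm3	ogm_gm3_m1	c1	1
ogm	gm3	ogm_gm3_m1	c3	2
ogm	gm3	ogm_gm3_m1	c5	3
ogm	gm3	ogm_gm3_m1	c7	4
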
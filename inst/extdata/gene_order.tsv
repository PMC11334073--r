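genome	gene	ordinal
gmR	r0	0
gmR	rf1	1
gm1	af0	0
gm1	af1	1
gm1	a2	2
gm1	af3	3
gm1	a4	4
gm1	af5	5
gm2	bf0	0
gm2	bf1	1
gm2	b2	2
gm2	bf3	3
gm2	bf4	4
gm2	bf5	5
gm2	bf6	6
gm2	b7	7
gm3	cf0	0
gm3	c1	1
gm3	cf2	2
gm3	c3	3
gm3	cf4	4
gm3	c5	5
gm3	cf6	6
gm3	c7	7
gm3	cf8	8
gm3	c9	9
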
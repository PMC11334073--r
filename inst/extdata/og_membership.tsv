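gene	family	genome
g1	og1	X
g2	og1	Y
g3	og2	X
g4	og2	Y
g5	og3	X
g6	og3	Y
r0	ogm	gmR
a2	ogm	gm1
a4	ogm	gm1
b2	ogm	gm2
b7	ogm	gm2
c1	ogm	gm3
c3	ogm	gm3
c5	ogm	gm3
c7	ogm	gm3
c9	ogm	gm3
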
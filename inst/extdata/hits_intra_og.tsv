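query	subject	evalue	bitscore
a2	r0	1e-10	200
a4	r0	1e-12	210
b2	r0	1e-10	200
b7	r0	1e-10	200
c1	r0	1e-10	200
c3	r0	1e-10	200
c5	r0	1e-10	200
c7	r0	1e-10	200
c9	r0	1e-10	200
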
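gene	length
r0	500
a2	100
a4	120
b2	100
b7	100
c1	100
c3	100
c5	100
c7	100
c9	100
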
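query	subject	evalue	bitscore	db
g1	cellA	1e-4	100	cellular
g3	cellB	1e-3	90	cellular
g4	cellC	1e-2	80	cellular
g6	gvogZ	1e-8	50	gvog
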
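position	residue
2	K
8	T
23	Q
29	F
36	N
42	G
47	R
53	S
58	D
64	H
70	E
81	M
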
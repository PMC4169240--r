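position	ref	alt
73	A	G
152	T	C
263	A	G
750	A	G
1438	A	G
4769	A	G
8860	A	G
15326	A	G
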
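201	A	C
401	C	T
601	T	C
701	A	T
801	C	A
1001	A	G
1101	T	A
1201	A	G
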
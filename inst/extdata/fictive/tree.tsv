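haplogroup	parent	defining_markers
Root
X	Root	M1
X1a	X	M2
Y	Root	M3
Z	Root	M4
Z1	Z	P5
Z2	Z	M6
Z2b	Z2	M7
Z2b*	Z2b
Z2b3a	Z2b	M8
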
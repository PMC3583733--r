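name	synonyms	rs_id	pos_hg18	pos_hg19	conversion
M1			98	101	A->G
M2	P2,Page2	rs1002	198	201	A->C
M3			298	301	G->A
M4			398	401	C->T
M5	P5		498	501	G->C
M6			598	601	T->C
M7			698	701	A->T
M8			798	801	C->A
IND1			898	901	4G->3G
V218			998	1001	A->G
MEH2			1048	1051	C->T
L999	S999		1098	1101	T->A
NOP1			1150		A->G
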
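@HD	VN:1.6	SO:queryname
@SQ	SN:chr1	LN:10000
@SQ	SN:chr2	LN:8000
r001	0	chr1	101	255	10M	*	0	0	ACGTACGTAC	IIIIIIIIII	MD:Z:10	NM:i:0
r001	256	chr2	501	255	10M	*	0	0	ACGTACGTAC	IIIIIIIIII	MD:Z:4T5	NM:i:1
r002	16	chr1	201	255	4M1D4M	*	0	0	ACGTACGT	IIIIIIII	MD:Z:4^G4	NM:i:1
r003	0	chr1	301	255	2S6M2S	*	0	0	TTACGTACTT	IIIIIIIIII	MD:Z:6	NM:i:0
r004	4	*	0	0	*	*	0	0	ACGTACGTAC	IIIIIIIIII
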
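signature	paper_symbol	canonical_symbol	direction
das	p16	CDKN2A	up
das	HMGA1	HMGA1	up
das	HMGA2	HMGA2	up
das	HIRA	HIRA	up
das	ASF1a	ASF1A	up
das	H2AFY	H2AFY	up
das	H2AFY2	H2AFY2	up
das	PML	PML	up
das	MMP3	MMP3	up
das	53BP1	TP53BP1	up
das	p21	CDKN1A	up
das	Ki67	MKI67	down
mss	IL6	IL6	up
mss	IL8	CXCL8	up
mss	PAI1	SERPINE1	up
mss	IGFBP3	IGFBP3	up
mss	IGFBP5	IGFBP5	up
mss	IGFBP7	IGFBP7	up
mss	IL1A	IL1A	up
mss	CXCR2	CXCR2	up
mss	IGF1	IGF1	down
mss	IGF2	IGF2	down
mss	WNT2	WNT2	down
mss	CAMP	CAMP	up
mss	STMN1	STMN1	up
mss	EEF1A1	EEF1A1	up
mss	IGF2R	IGF2R	up
mss	TGFB1	TGFB1	up
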
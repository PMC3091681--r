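alias	canonical_symbol
p16	CDKN2A
P16	CDKN2A
INK4A	CDKN2A
CDKN2	CDKN2A
p21	CDKN1A
P21	CDKN1A
CIP1	CDKN1A
WAF1	CDKN1A
PAI1	SERPINE1
PAI-1	SERPINE1
53BP1	TP53BP1
Ki67	MKI67
KI67	MKI67
KI-67	MKI67
MIB1	MKI67
IL8	CXCL8
IL-8	CXCL8
IL-6	IL6
IL-1A	IL1A
IL1-alpha	IL1A
ASF1a	ASF1A
HIR	HIRA
MACROH2A1	H2AFY
MACROH2A2	H2AFY2
STLS	MMP3
TGFB	TGFB1
CAP18	CAMP
LL37	CAMP
EF1A	EEF1A1
OP18	STMN1
IGF-1	IGF1
IGF-2	IGF2
IGF2-R	IGF2R
CD222	IGF2R
IL8RB	CXCR2
CD182	CXCR2
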
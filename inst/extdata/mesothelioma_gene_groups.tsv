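gene_group	paper_symbol	canonical_symbol	duplicated_across_groups
1	CAMP	CAMP	FALSE
1	EEF1A1	EEF1A1	TRUE
1	IGF2R	IGF2R	FALSE
1	IL1A	IL1A	FALSE
1	IL6	IL6	FALSE
1	IL8	CXCL8	FALSE
1	CXCR2	CXCR2	TRUE
1	WNT2	WNT2	FALSE
2	EEF1A1	EEF1A1	TRUE
2	IGF1	IGF1	FALSE
2	IGF2	IGF2	FALSE
2	IGFBP3	IGFBP3	FALSE
2	IGFBP5	IGFBP5	FALSE
2	IGFBP7	IGFBP7	FALSE
2	CXCR2	CXCR2	TRUE
2	PAI1	SERPINE1	FALSE
2	STMN1	STMN1	FALSE
2	TGFB1	TGFB1	FALSE
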
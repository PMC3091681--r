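probe_id	symbol
PRB001	CDKN2A
PRB002	HMGA1
PRB003	HMGA2
PRB004	HIRA
PRB005	ASF1A
PRB006	H2AFY
PRB007	H2AFY2
PRB008	PML
PRB009	MMP3
PRB010	TP53BP1
PRB011	CDKN1A
PRB012	MKI67
PRB013	IL6
PRB014	CXCL8
PRB015	SERPINE1
PRB016	IGFBP3
PRB017	IGFBP5
PRB018	IGFBP7
PRB019	IL1A
PRB020	CXCR2
PRB021	IGF1
PRB022	IGF2
PRB023	WNT2
PRB024	CAMP
PRB025	STMN1
PRB026	EEF1A1
PRB027	IGF2R
PRB028	TGFB1
PRB029	BG0001
PRB030	BG0002
PRB031	BG0003
PRB032	BG0004
PRB900	CDKN2A
PRB901	HMGA1
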
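!Series_title	"synthetic senescence scoring fixture"
!Series_summary	"fully synthetic data generated by senescore generators; not a real GEO series"
!series_matrix_table_begin
"ID_REF"	"SMP1"	"SMP2"	"SMP3"	"SMP4"	"SMP5"	"SMP6"
"PRB001"	92.2982	92.2982	92.2982	369.193	369.193	369.193
"PRB002"	152.137	608.549	608.549	152.137	608.549	152.137
"PRB003"	1198.28		4793.11	1198.28	4793.11	1198.28
"PRB004"	375.971	375.971	1503.88	1503.88	1503.88	375.971
"PRB005"	11.8141	11.8141	47.2562	47.2562	47.2562	11.8141
"PRB006"	538.211	538.211	2152.84	2152.84	2152.84	538.211
"PRB007"	179.126	179.126	716.504	716.504	716.504	179.126
"PRB008"	221.557	886.228	221.557	221.557	886.228	886.228
"PRB009"	139.322	139.322	139.322	557.286	557.286	557.286
"PRB010"	521.571	521.571	521.571	2086.29	2086.29	2086.29
"PRB011"	160.925	160.925	160.925	643.702	643.702	643.702
"PRB012"	1012.18	1012.18	1012.18	253.046	253.046	253.046
"PRB013"	154.543	154.543	154.543	618.172	618.172	618.172
"PRB014"	1197.72	4790.89	1197.72	1197.72	4790.89	4790.89
"PRB015"	366.174	366.174	 1464.7	 1464.7	 1464.7	366.174
"PRB016"	262.225	 1048.9	 1048.9	262.225	 1048.9	262.225
"PRB017"	934.532	3738.13	934.532	934.532	3738.13	3738.13
"PRB018"	246.728	246.728	246.728	986.914	986.914	986.914
"PRB019"	60.3322	60.3322	241.329	241.329	241.329	60.3322
"PRB020"	276.397	276.397	276.397	1105.59	1105.59	1105.59
"PRB021"	198.314	198.314	49.5785	49.5785	49.5785	198.314
"PRB022"	1742.73	1742.73	435.683	435.683	435.683	1742.73
"PRB023"	1994.22	1994.22	1994.22	498.555	498.555	498.555
"PRB024"	994.795	3979.18	3979.18	994.795	3979.18	994.795
"PRB025"	71.2669	71.2669	285.067	285.067	285.067	71.2669
"PRB026"	127.811	127.811	127.811	511.242	511.242	511.242
"PRB027"	 154.33	 154.33	617.318	617.318	617.318	 154.33
"PRB028"	430.532	430.532	430.532	1722.13	1722.13	1722.13
"PRB029"	 38.362	59.1993	104.763	45.8609	33.0634	56.4333
"PRB030"	507.847	372.429	 466.54	954.542	877.043	631.967
"PRB031"	293.164	514.733	 639.07	260.228	 467.95	331.875
"PRB032"	153.889	248.496	 258.88	76.7056	160.077	208.531
"PRB900"	101.528	101.528	101.528	406.112	406.112	406.112
"PRB901"	167.351	669.404	669.404	167.351	669.404	167.351
"PRB999"	106.095	145.131	183.876	157.464	135.335	154.743
!series_matrix_table_end
!series_end
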
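sample	fraction_all	fraction_das	fraction_mss
SMP1	0	0	0
SMP2	0.25	0.25	0.25
SMP3	0.5	0.5	0.5
SMP4	0.75	0.75	0.75
SMP5	1	1	1
SMP6	0.5	0.5	0.5
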
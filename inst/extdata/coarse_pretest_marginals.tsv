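bin_lower	bin_upper	proportion
0	0.010	0.417
0.01	0.015	0.218
0.015	0.020	0.157
0.02	0.025	0.094
0.025	0.030	0.046
0.03	0.040	0.046
0.04	inf	0.023
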
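organism	sample_A	sample_B
ecoli	0.05	0.20
yeast	0.30	0.15
human	0.65	0.65
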
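target	score12	talaris2014	ref2015
1abc	0.20	0.55	0.90
2xyz	0.40	0.80	NA
3pqr	0.10	0.45	0.70
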
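SEQUENCE:
SCORE: total_score rmsd description
SCORE: -15.250 0.820 model_0001
SCORE: corrupted_value 2.450 model_0002
SCORE: -3.700 11.300 model_0003
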
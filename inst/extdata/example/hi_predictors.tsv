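symbol	predictor_calls
GENE0001	1,1,1,0,0
GENE0002	0,1,0,0,0
GENE0003	0,0,0,0,0
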
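NN   0.99
NSF  0.005
NER  0.005
MM 0.9998
MI 0.0001
MD 0.0001
II    0.2
IM    0.8
GE   0.01
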
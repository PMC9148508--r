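start    0.2    0.2    0.2    0.2    0.2
stop    0.2    0.2    0.2    0.2    0.2
start1    0.2    0.2    0.2    0.2    0.2
stop1    0.2    0.2    0.2    0.2    0.2
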
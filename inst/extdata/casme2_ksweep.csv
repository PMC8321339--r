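K,n_correct,n_total
1,79,255
2,127,255
3,169,255
5,210,255
8,226,255
10,228,255
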
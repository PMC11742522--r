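"age_lo","age_hi","weight"
0,17,0.2
18,29,0.34
30,44,0.3
45,64,0.13
65,84,0.03
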
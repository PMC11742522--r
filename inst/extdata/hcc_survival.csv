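"years_since_dx","annual_death_prob"
0,0.55
1,0.35
2,0.25
3,0.18
4,0.14
5,0.11
6,0.09
7,0.08
8,0.07
9,0.06
10,0.05
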
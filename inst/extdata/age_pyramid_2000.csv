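"age","weight"
0,0.013627932
1,0.013627932
2,0.013627932
3,0.013627932
4,0.013627932
5,0.014604402
6,0.014604402
7,0.014604402
8,0.014604402
9,0.014604402
10,0.014588767
11,0.014588767
12,0.014588767
13,0.014588767
14,0.014588767
15,0.014369879
16,0.014369879
17,0.014369879
18,0.014369879
19,0.014369879
20,0.013477269
21,0.013477269
22,0.013477269
23,0.013477269
24,0.013477269
25,0.013773621
26,0.013773621
27,0.013773621
28,0.013773621
29,0.013773621
30,0.014575975
31,0.014575975
32,0.014575975
33,0.014575975
34,0.014575975
35,0.016137331
36,0.016137331
37,0.016137331
38,0.016137331
39,0.016137331
40,0.015949002
41,0.015949002
42,0.015949002
43,0.015949002
44,0.015949002
45,0.014278912
46,0.014278912
47,0.014278912
48,0.014278912
49,0.014278912
50,0.012497957
51,0.012497957
52,0.012497957
53,0.012497957
54,0.012497957
55,0.0095721017
56,0.0095721017
57,0.0095721017
58,0.0095721017
59,0.0095721017
60,0.0076788595
61,0.0076788595
62,0.0076788595
63,0.0076788595
64,0.0076788595
65,0.0067755897
66,0.0067755897
67,0.0067755897
68,0.0067755897
69,0.0067755897
70,0.0062944617
71,0.0062944617
72,0.0062944617
73,0.0062944617
74,0.0062944617
75,0.0052703769
76,0.0052703769
77,0.0052703769
78,0.0052703769
79,0.0052703769
80,0.0035142953
81,0.0035142953
82,0.0035142953
83,0.0035142953
84,0.0035142953
85,0.0031005408
86,0.0024804326
87,0.0019843461
88,0.0015874769
89,0.0012699815
90,0.0010159852
91,0.00081278817
92,0.00065023053
93,0.00052018443
94,0.00041614754
95,0.00033291803
96,0.00026633443
97,0.00021306754
98,0.00017045403
99,0.00013636323
100,0.00010909058
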
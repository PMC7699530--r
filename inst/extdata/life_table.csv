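age,qx
40,5.49e-4
41,6.11e-4
42,6.81e-4
43,7.58e-4
44,8.45e-4
45,9.41e-4
46,0.001048
47,0.001167
48,0.0013
49,0.001448
50,0.001612
51,0.001796
52,0.002
53,0.002228
54,0.002481
55,0.002763
56,0.003078
57,0.003428
58,0.003818
59,0.004252
60,0.004736
61,0.005274
62,0.005874
63,0.006543
64,0.007287
65,0.008116
66,0.009039
67,0.010068
68,0.011213
69,0.012489
70,0.01391
71,0.015492
72,0.017254
73,0.019217
74,0.021404
75,0.023839
76,0.026551
77,0.029571
78,0.032935
79,0.036682
80,0.040855
81,0.045503
82,0.05068
83,0.056445
84,0.062867
85,0.070019
86,0.077984
87,0.086856
88,0.096737
89,0.107743
90,0.12
91,0.133652
92,0.148857
93,0.165791
94,0.184652
95,0.205659
96,0.229056
97,0.255115
98,0.284138
99,0.316463
100,0.352465
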
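patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,0.247,0.223,10.90,0.168,0.137,22.12
2,0.285,0.253,12.68,0.091,0.084,7.91
3,0.294,0.255,15.29,0.142,0.121,17.59
4,0.175,0.161,8.94,0.109,0.095,14.78
5,0.213,0.185,15.25,0.135,0.114,18.84
6,0.271,0.259,4.82,0.146,0.136,7.46
7,0.342,0.319,7.25,0.178,0.158,12.58
8,0.227,0.199,13.93,0.151,0.125,20.82
9,0.241,0.205,17.68,0.104,0.090,15.23
10,0.245,0.215,14.32,0.114,0.096,19.03
11,0.133,0.125,6.69,0.086,0.078,9.85
12,0.299,0.270,10.80,0.103,0.094,8.84
13,0.180,0.163,9.84,0.104,0.096,8.43
14,0.175,0.152,14.87,0.114,0.096,18.05
15,0.200,0.185,8.10,0.098,0.091,7.59
16,0.176,0.182,-3.71,0.074,0.073,0.91
17,0.177,0.163,8.49,0.093,0.083,12.96
18,0.473,0.461,2.66,0.112,0.104,7.78
19,0.285,0.259,10.09,0.116,0.107,8.15
20,0.286,0.258,10.82,0.133,0.120,10.75
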
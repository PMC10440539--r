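patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,0.247,0.223,10.90,0.158,0.126,25.44
2,0.285,0.253,12.68,0.146,0.124,17.90
3,0.294,0.255,15.29,0.134,0.112,19.24
4,0.202,0.174,15.62,0.125,0.105,18.54
5,0.219,0.191,14.92,0.150,0.117,27.99
6,0.271,0.259,4.82,0.149,0.130,14.46
7,0.342,0.319,7.25,0.166,0.145,14.52
8,0.227,0.199,13.93,0.151,0.119,26.86
9,0.241,0.205,17.68,0.113,0.092,22.15
10,0.275,0.224,22.81,0.149,0.121,23.33
11,0.174,0.141,23.69,0.115,0.094,21.94
12,0.299,0.270,10.80,0.126,0.108,16.73
13,0.231,0.205,12.62,0.138,0.118,16.12
14,0.198,0.171,15.85,0.142,0.116,22.84
15,0.253,0.231,9.63,0.145,0.127,13.89
16,0.272,0.253,7.55,0.121,0.100,20.82
17,0.192,0.163,17.99,0.120,0.095,26.66
18,0.473,0.461,2.66,0.109,0.099,10.74
19,0.307,0.287,7.12,0.101,0.093,8.15
20,0.286,0.258,10.82,0.108,0.097,11.37
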
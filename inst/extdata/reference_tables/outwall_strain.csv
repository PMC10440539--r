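patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,0.171,0.078,118.02,0.099,0.055,81.22
2,0.212,0.096,121.27,0.092,0.055,67.04
3,0.158,0.080,96.23,0.072,0.053,36.12
4,0.131,0.061,115.68,0.060,0.051,17.56
5,0.173,0.072,139.94,0.117,0.054,114.91
6,0.151,0.073,107.86,0.072,0.052,36.37
7,0.166,0.072,130.64,0.089,0.052,72.57
8,0.211,0.098,115.70,0.101,0.057,79.30
9,0.161,0.081,98.70,0.064,0.052,22.80
10,0.201,0.098,103.95,0.106,0.056,88.76
11,0.140,0.069,104.20,0.072,0.053,36.09
12,0.160,0.090,78.01,0.073,0.054,35.58
13,0.159,0.080,98.89,0.078,0.055,41.90
14,0.175,0.104,68.78,0.096,0.059,63.32
15,0.156,0.094,65.19,0.082,0.057,42.42
16,0.140,0.065,115.72,0.065,0.052,27.00
17,0.155,0.082,88.18,0.072,0.053,35.93
18,0.106,0.061,71.95,0.055,0.051,7.11
19,0.101,0.051,97.30,0.054,0.051,4.54
20,0.190,0.053,261.90,0.058,0.051,13.68
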
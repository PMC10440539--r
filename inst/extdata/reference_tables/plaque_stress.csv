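patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,467.36,279.88,66.99,176.91,109.97,60.87
2,381.40,277.28,37.55,146.13,103.47,41.24
3,289.47,201.25,43.84,118.20,86.70,36.34
4,261.41,173.43,50.73,101.99,77.71,31.25
5,362.32,240.66,50.55,160.32,100.50,59.51
6,388.89,323.54,20.20,150.27,114.24,31.53
7,684.90,523.80,30.76,190.35,139.14,36.80
8,490.42,319.88,53.31,165.07,104.52,57.92
9,322.70,199.48,61.77,96.91,71.58,35.39
10,504.88,316.96,59.29,166.36,106.23,56.59
11,198.05,118.12,67.67,95.64,73.59,29.96
12,408.69,290.87,40.51,117.94,89.84,31.28
13,340.09,251.97,34.97,131.55,96.28,36.63
14,305.10,161.21,89.26,139.06,95.83,45.11
15,432.01,316.37,36.55,150.62,110.79,35.96
16,321.55,257.06,25.09,120.71,88.56,36.30
17,262.60,140.37,87.07,104.65,74.08,41.27
18,486.95,424.14,14.81,87.11,74.64,16.71
19,355.37,268.27,32.47,78.06,68.60,13.79
20,438.45,333.73,31.38,93.89,79.17,18.59
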
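patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,467.36,279.88,66.99,212.51,131.23,61.93
2,381.40,277.28,37.55,103.76,82.69,25.47
3,289.47,201.25,43.84,131.38,96.25,36.49
4,164.02,129.00,27.15,86.71,71.15,21.87
5,362.32,240.66,50.55,147.76,102.58,44.05
6,388.89,323.54,20.20,149.10,127.78,16.68
7,684.90,523.80,30.76,228.43,168.23,35.79
8,490.42,319.88,53.31,186.65,122.68,52.15
9,322.70,199.48,61.77,91.47,73.05,25.20
10,504.88,316.96,59.29,133.75,92.06,45.28
11,100.67,92.55,8.77,69.77,62.73,11.23
12,408.69,290.87,40.51,98.57,82.11,20.04
13,158.97,135.50,17.32,80.57,71.19,13.17
14,205.56,128.05,60.53,107.36,82.71,29.80
15,289.30,227.39,27.23,86.39,75.52,14.39
16,197.51,169.89,16.26,84.78,79.34,6.86
17,169.42,139.93,21.08,72.49,63.84,13.55
18,486.95,424.14,14.81,92.27,80.86,14.11
19,296.57,238.49,24.35,105.04,90.65,15.87
20,438.45,333.73,31.38,128.35,106.53,20.48
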
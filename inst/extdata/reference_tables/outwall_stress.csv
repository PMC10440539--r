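patient,multi_max,single_max,diff_max_pct,multi_mean,single_mean,diff_mean_pct
1,33.63,79.42,-57.66,18.77,58.84,-68.11
2,63.73,89.32,-28.65,18.35,58.49,-68.63
3,31.43,80.73,-61.07,13.82,50.71,-72.74
4,24.03,64.34,-62.65,11.05,45.75,-75.85
5,30.92,77.76,-60.23,21.42,62.24,-65.58
6,32.45,80.03,-59.45,12.83,49.07,-73.85
7,28.92,72.13,-59.90,15.61,55.05,-71.65
8,54.21,91.84,-40.98,20.54,59.48,-65.46
9,34.88,76.54,-54.44,10.54,43.88,-75.97
10,43.74,86.38,-49.37,21.83,63.08,-65.39
11,27.53,71.38,-61.43,13.24,48.69,-72.80
12,35.35,89.72,-60.60,12.96,49.75,-73.96
13,32.38,81.33,-60.19,14.84,52.62,-71.80
14,42.95,93.20,-53.91,20.20,60.78,-66.77
15,39.77,91.31,-56.45,17.19,57.23,-69.97
16,27.49,68.31,-59.76,12.26,46.76,-73.77
17,39.40,81.64,-51.74,13.74,48.63,-71.74
18,24.90,62.47,-60.14,8.61,40.85,-78.92
19,14.85,47.79,-68.94,6.34,36.80,-82.78
20,32.73,62.00,-47.21,8.34,40.61,-79.48
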
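sex,age_months,median_cm,sd_cm
male,6,67.6,2.3
male,7,69.1,2.35
male,8,70.54,2.4
male,9,71.91,2.45
male,10,73.23,2.5
male,11,74.49,2.55
male,12,75.7,2.6
male,13,76.86,2.65
male,14,77.97,2.7
male,15,79.04,2.75
male,16,80.06,2.8
male,17,81.05,2.85
male,18,82,2.9
male,19,82.92,2.95
male,20,83.8,3
male,21,84.66,3.05
male,22,85.5,3.1
male,23,86.31,3.15
male,24,87.1,3.2
male,25,87.88,3.25
male,26,88.64,3.3
male,27,89.39,3.35
male,28,90.13,3.4
male,29,90.87,3.45
male,30,91.6,3.5
male,31,92.33,3.55
male,32,93.07,3.6
male,33,93.81,3.65
male,34,94.56,3.7
male,35,95.32,3.75
male,36,96.1,3.8
female,6,65.7,2.3
female,7,67.24,2.35
female,8,68.71,2.41
female,9,70.12,2.46
female,10,71.47,2.51
female,11,72.76,2.57
female,12,74,2.62
female,13,75.19,2.67
female,14,76.33,2.73
female,15,77.42,2.78
female,16,78.47,2.83
female,17,79.48,2.89
female,18,80.46,2.94
female,19,81.4,2.99
female,20,82.31,3.05
female,21,83.19,3.1
female,22,84.05,3.15
female,23,84.88,3.21
female,24,85.7,3.26
female,25,86.5,3.31
female,26,87.29,3.37
female,27,88.07,3.42
female,28,88.84,3.47
female,29,89.6,3.53
female,30,90.37,3.58
female,31,91.14,3.63
female,32,91.91,3.69
female,33,92.69,3.74
female,34,93.48,3.79
female,35,94.28,3.85
female,36,95.1,3.9
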
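bap_uM,iba_uM,pg_mM,sucrose_mM,pr_mean,pr_se,sn_mean,sn_se,sl_mean,sl_se,bcw_mean,bcw_se
0,0,0,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0,43.82,31.11,3.51,1.33,0.14,2.40,0.13,0.00,0.00
2.22,0.25,0,43.82,33.33,3.33,1.56,0.15,2.69,0.15,0.00,0.00
2.22,0.49,0,43.82,28.89,3.51,1.39,0.16,2.57,0.17,0.00,0.00
4.44,0,0,43.82,40.00,5.77,1.53,0.23,2.74,0.17,0.04,0.02
4.44,0.25,0,43.82,42.22,5.21,1.72,0.21,2.96,0.18,0.10,0.03
4.44,0.49,0,43.82,55.56,2.94,1.87,0.17,2.89,0.15,0.16,0.04
0,0,0.2,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.2,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.2,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.2,43.82,48.89,4.84,1.80,0.20,2.81,0.16,0.00,0.00
2.22,0.25,0.2,43.82,62.22,5.21,2.83,0.22,3.01,0.16,0.00,0.00
2.22,0.49,0.2,43.82,55.56,4.44,2.56,0.28,3.21,0.19,0.00,0.00
4.44,0,0.2,43.82,31.11,3.51,1.33,0.14,2.74,0.17,0.08,0.03
4.44,0.25,0.2,43.82,40.00,4.71,2.07,0.20,3.32,0.14,0.16,0.04
4.44,0.49,0.2,43.82,55.56,4.44,3.07,0.20,3.79,0.15,0.21,0.04
0,0,0.4,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.4,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.4,43.82,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.4,43.82,57.78,5.21,2.66,0.18,3.46,0.14,0.00,0.00
2.22,0.25,0.4,43.82,53.33,6.67,2.76,0.21,3.63,0.14,0.00,0.00
2.22,0.49,0.4,43.82,64.44,5.56,3.64,0.10,4.06,0.11,0.00,0.00
4.44,0,0.4,43.82,44.44,4.44,2.26,0.15,3.68,0.15,0.13,0.02
4.44,0.25,0.4,43.82,71.11,3.51,3.66,0.15,3.71,0.13,0.22,0.04
4.44,0.49,0.4,43.82,62.22,4.01,3.41,0.13,3.92,0.15,0.28,0.05
0,0,0,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0,87.64,60.00,4.71,5.52,0.21,3.30,0.12,0.00,0.00
2.22,0.25,0,87.64,51.11,4.84,5.43,0.12,3.50,0.10,0.04,0.02
2.22,0.49,0,87.64,48.89,3.51,3.10,0.26,4.18,0.17,0.09,0.03
4.44,0,0,87.64,53.33,5.77,2.80,0.34,3.59,0.11,0.10,0.02
4.44,0.25,0,87.64,57.78,5.21,2.63,0.21,3.94,0.09,0.10,0.03
4.44,0.49,0,87.64,60.00,5.77,3.09,0.29,4.62,0.12,0.17,0.04
0,0,0.2,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.2,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.2,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.2,87.64,93.33,3.33,8.82,0.16,4.20,0.15,0.00,0.00
2.22,0.25,0.2,87.64,100.00,0.00,12.76,0.25,4.60,0.14,0.07,0.02
2.22,0.49,0.2,87.64,100.00,0.00,11.46,0.20,4.82,0.13,0.07,0.02
4.44,0,0.2,87.64,84.44,4.44,6.76,0.14,4.84,0.15,0.11,0.03
4.44,0.25,0.2,87.64,95.56,2.94,8.19,0.16,5.10,0.09,0.19,0.04
4.44,0.49,0.2,87.64,100.00,0.00,9.10,0.15,5.74,0.11,0.24,0.03
0,0,0.4,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.4,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.4,87.64,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.4,87.64,91.11,3.51,8.62,0.11,5.06,0.12,0.00,0.00
2.22,0.25,0.4,87.64,100.00,0.00,11.43,0.18,4.77,0.17,0.13,0.03
2.22,0.49,0.4,87.64,95.56,2.94,9.76,0.18,5.63,0.13,0.19,0.03
4.44,0,0.4,87.64,86.67,3.33,6.39,0.15,5.54,0.17,0.21,0.02
4.44,0.25,0.4,87.64,91.11,3.51,7.87,0.15,5.70,0.13,0.32,0.03
4.44,0.49,0.4,87.64,100.00,0.00,8.59,0.14,5.89,0.13,0.40,0.03
0,0,0,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0,131.46,46.67,3.33,4.04,0.21,3.22,0.14,0.00,0.00
2.22,0.25,0,131.46,44.44,2.94,5.04,0.08,3.18,0.09,0.03,0.02
2.22,0.49,0,131.46,40.00,3.33,2.51,0.19,3.79,0.17,0.08,0.04
4.44,0,0,131.46,42.22,5.21,2.33,0.28,3.43,0.10,0.06,0.02
4.44,0.25,0,131.46,53.33,4.71,2.32,0.18,3.54,0.14,0.08,0.03
4.44,0.49,0,131.46,53.33,4.71,2.39,0.38,4.07,0.12,0.12,0.03
0,0,0.2,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.2,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.2,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.2,131.46,84.44,4.44,8.40,0.14,3.49,0.09,0.00,0.00
2.22,0.25,0.2,131.46,95.56,2.94,10.76,0.21,3.81,0.16,0.03,0.02
2.22,0.49,0.2,131.46,91.11,3.51,9.09,0.16,4.23,0.08,0.07,0.02
4.44,0,0.2,131.46,73.33,4.71,5.68,0.14,4.60,0.13,0.09,0.03
4.44,0.25,0.2,131.46,86.67,4.71,7.61,0.12,5.10,0.09,0.17,0.02
4.44,0.49,0.2,131.46,93.33,3.33,8.59,0.17,5.34,0.12,0.19,0.03
0,0,0.4,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.25,0.4,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
0,0.49,0.4,131.46,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
2.22,0,0.4,131.46,80.00,3.33,6.76,0.18,4.58,0.15,0.00,0.00
2.22,0.25,0.4,131.46,91.11,3.51,9.57,0.19,4.71,0.10,0.09,0.02
2.22,0.49,0.4,131.46,86.67,4.71,8.49,0.23,4.70,0.19,0.14,0.03
4.44,0,0.4,131.46,77.78,5.21,5.61,0.14,5.33,0.15,0.13,0.03
4.44,0.25,0.4,131.46,80.00,4.71,7.11,0.16,4.94,0.23,0.21,0.04
4.44,0.49,0.4,131.46,84.44,5.56,7.59,0.16,5.22,0.24,0.27,0.04
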
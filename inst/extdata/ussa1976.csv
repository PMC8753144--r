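z_m,rho_kg_m3,T_K,mfp_m
0,1.225,288.15,6.63323e-08
2000,1.00655,275.154,8.0728e-08
4000,0.819346,262.166,9.9173e-08
6000,0.660111,249.187,1.23096e-07
8000,0.525786,236.215,1.54544e-07
10000,0.41351,223.252,1.96505e-07
12000,0.311938,216.65,2.60491e-07
14000,0.227856,216.65,3.56616e-07
16000,0.166471,216.65,4.88116e-07
18000,0.121647,216.65,6.67974e-07
20000,0.0889099,216.65,9.13926e-07
22000,0.0645098,218.574,1.25961e-06
24000,0.0469379,220.56,1.73116e-06
26000,0.0342566,222.544,2.37201e-06
28000,0.0250763,224.527,3.24039e-06
30000,0.0184102,226.509,4.4137e-06
32000,0.0135552,228.49,5.99455e-06
34000,0.0098874,233.744,8.21824e-06
36000,0.00725792,239.282,1.11956e-05
38000,0.00536656,244.818,1.51414e-05
40000,0.00399568,250.35,2.03362e-05
42000,0.00299476,255.878,2.7133e-05
44000,0.00225885,261.403,3.59727e-05
46000,0.00171415,266.925,4.74038e-05
48000,0.0013167,270.65,6.17126e-05
50000,0.00102688,270.65,7.91302e-05
52000,0.000805616,269.031,0.000100863
54000,0.000639004,263.524,0.000127162
56000,0.00050445,258.019,0.00016108
58000,0.000396264,252.518,0.000205058
60000,0.000309678,247.021,0.000262392
62000,0.00024071,241.527,0.000337572
64000,0.000186051,236.036,0.000436747
66000,0.000142958,230.549,0.0005684
68000,0.000109169,225.065,0.000744322
70000,8.28286e-05,219.585,0.000981026
72000,6.23732e-05,214.263,0.00130276
74000,4.63853e-05,210.353,0.00175179
76000,3.43108e-05,206.446,0.00236826
78000,2.52385e-05,202.541,0.00321957
80000,1.8458e-05,198.639,0.00440226
82000,1.34183e-05,194.739,0.00605568
84000,9.69387e-06,190.841,0.00838231
86000,6.958e-06,186.87,0.0116724
90000,3.416e-06,186.87,0.0237425
95000,1.393e-06,188.42,0.0578603
100000,5.604e-07,195.08,0.142173
105000,2.325e-07,208.84,0.336408
110000,9.708e-08,240,0.788046
115000,4.289e-08,300,1.74512
120000,2.222e-08,360,3.30791
130000,8.152e-09,469.27,8.75486
140000,3.831e-09,559.63,18.1242
150000,2.076e-09,634.39,32.5676
160000,1.233e-09,696.29,53.4461
170000,7.815e-10,747.57,82.3136
180000,5.194e-10,790.07,121.528
190000,3.581e-10,825.31,172.351
200000,2.541e-10,854.56,237.372
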
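age,lat_mof,it_mof,uat_mof,lat_hip,it_hip,uat_hip
40,1.02,2.35,2.82,0.05,0.28,0.30
45,1.29,2.89,3.47,0.08,0.35,0.42
50,1.66,3.62,4.34,0.12,0.49,0.59
55,2.16,4.60,5.52,0.22,0.74,0.89
60,2.82,5.86,7.03,0.40,1.16,1.39
65,3.51,7.06,8.47,0.73,1.81,2.17
70,4.33,8.31,9.97,1.31,2.78,3.34
75,5.41,9.70,11.64,2.14,3.87,4.64
80,6.59,10.92,13.10,2.81,4.34,5.21
85,7.67,12.64,15.17,3.14,4.84,5.81
90,8.36,13.69,16.43,3.27,5.04,6.05
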
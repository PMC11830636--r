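sex,age_low,age_high,ratio
F,40,45,8
F,45,50,7.8
F,50,55,7.2
F,55,60,6.5
F,60,65,5.6
F,65,70,4.7
F,70,75,3.8
F,75,80,3
F,80,85,2.4
F,85,90,2
F,90,,1.8
M,40,45,6
M,45,50,5.8
M,50,55,5.3
M,55,60,4.8
M,60,65,4.2
M,65,70,3.6
M,70,75,3
M,75,80,2.5
M,80,85,2.1
M,85,90,1.8
M,90,,1.6
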
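sex,age_low,age_high,rate
F,40,45,122.604155518977
F,45,50,197.149222745269
F,50,55,317.01874919768
F,55,60,509.770649579054
F,60,65,819.718441984668
F,65,70,1318.11889265227
F,70,75,2119.55389335909
F,75,80,3408.27275285769
F,80,85,5480.55097549912
F,85,90,8812.80377864713
F,90,,14171.1135957209
M,40,45,280.036031334152
M,45,50,439.183920317657
M,50,55,688.777493905525
M,55,60,1080.21813678342
M,60,65,1694.11926690492
M,65,70,2656.90788996065
M,70,75,4166.86101955027
M,75,80,6534.93891220467
M,80,85,10248.8243274444
M,85,90,16073.3560796792
M,90,,25208.0402014834
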
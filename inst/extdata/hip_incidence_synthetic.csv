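sex,age_low,age_high,rate
F,40,45,14.1709965822304
F,45,50,23.3640234921421
F,50,55,38.5207625006322
F,55,60,63.5100004983802
F,60,65,104.710288723855
F,65,70,172.638080280172
F,70,75,284.632075090756
F,75,80,469.278956525645
F,80,85,773.710197515792
F,85,90,1275.63246000188
F,90,,2103.16237040064
M,40,45,13.2153076066499
M,45,50,20.2140079080363
M,50,55,30.9191528391321
M,55,60,47.2936399668442
M,60,65,72.339898604294
M,65,70,110.650415864548
M,70,75,169.249816038182
M,75,80,258.882897141792
M,80,85,395.984799282785
M,85,90,605.694555315275
M,90,,926.464589052514
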
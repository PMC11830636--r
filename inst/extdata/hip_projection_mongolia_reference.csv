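year,sex,count
2015,M,146
2015,F,294
2020,M,180
2020,F,350
2030,M,264
2030,F,553
2040,M,400
2040,F,933
2050,M,539
2050,F,1357
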
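sex,group,n
M,all,202
M,prior_fracture,93
M,low_risk,87
M,bmd_test_recommended,21
M,between_it_uat,0
M,high_risk,1
F,all,287
F,prior_fracture,102
F,low_risk,57
F,bmd_test_recommended,108
F,between_it_uat,8
F,high_risk,12
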
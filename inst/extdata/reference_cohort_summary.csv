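group,total,failing,above,failing_above,mean_pass,sd_pass,mean_fail,sd_fail
All,711,62,75,27,0.132,0.036,0.170,0.040
Head and Neck,366,25,31,8,0.141,0.030,0.167,0.026
Brain,63,12,8,5,0.117,0.032,0.172,0.053
Brain SBRT,19,7,12,7,0.176,0.037,0.216,0.029
Liver,22,1,1,0,0.129,0.049,0.159,
Liver SBRT,28,2,4,0,0.130,0.046,0.145,0.019
Lung,37,2,1,0,0.115,0.032,0.146,0.011
Lung SBRT,10,0,2,0,0.145,0.029,,
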
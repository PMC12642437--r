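name	value
mn_IP	5.16348026935485
mn_GM	0.0467518666944547
mn_VL	0.33225525030592
mn_TA	2.0675913433141
mn_SO	0.259309145213123
mn_BF	2.90558050753254
mn_GA	0.0663390919945814
kFv	0.0483293049209736
kFl	0.285041318927646
kEf	0
eta_v	1.68105312898687
eta_l	1.27244736670745
eta_f	0
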
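name	value
mn_IP	5.77106421602092
mn_GM	0.0369921067763432
mn_VL	0.257039319782808
mn_TA	3.32352551562055
mn_SO	0.195233517682041
mn_BF	2.68987798309566
mn_GA	0.270516663081241
kFv	0
kFl	0.145687618295742
kEf	2.82455991391262
eta_v	0
eta_l	1.19875625740893
eta_f	0.317623290247488
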
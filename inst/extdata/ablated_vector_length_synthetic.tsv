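name	value
mn_IP	5.10930346739866
mn_GM	0.0871779810678764
mn_VL	0.269379145378922
mn_TA	2.82261540477763
mn_SO	0.175170792919401
mn_BF	2.48620071129639
mn_GA	0.0750249793734566
kFv	0.127323537606328
kFl	0
kEf	2.96544518107175
eta_v	1.37247950207138
eta_l	0
eta_f	0.257037806393214
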
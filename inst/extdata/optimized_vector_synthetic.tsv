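name	value
mn_IP	5.41533660876053
mn_GM	0.223679506972669
mn_VL	0.336664166240505
mn_TA	2.43089568025763
mn_SO	0.102294603799789
mn_BF	2.95438327447278
mn_GA	0.212953282908517
kFv	0.108151659194345
kFl	0.217032456083231
kEf	2.80263248857303
eta_v	1.53941447174432
eta_l	1.29823619853872
eta_f	0.329432284467433
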
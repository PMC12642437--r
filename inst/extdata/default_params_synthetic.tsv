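network.C	20
network.ENa	55
network.ESynE	-10
network.gSynE	10
network.gSynI	10
network.Vth	-50
network.Vmax	0
network.class.RG.gNaP	5
network.class.RG.gLeak	4.5
network.class.RG.ELeak	-62.5
network.class.RG.ESynI	-75
network.class.IN.gNaP	0
network.class.IN.gLeak	5
network.class.IN.ELeak	-60
network.class.IN.ESynI	-75
network.class.CIN.gNaP	0
network.class.CIN.gLeak	5
network.class.CIN.ELeak	-60
network.class.CIN.ESynI	-75
network.class.PF.gNaP	0.5
network.class.PF.gLeak	5
network.class.PF.ELeak	-60
network.class.PF.ESynI	-75
network.class.MN.gNaP	0.29999999999999999
network.class.MN.gLeak	5
network.class.MN.ELeak	-60
network.class.MN.ESynI	-75
weights.a_rgf_inf	1.2
weights.a_rge_ine	0.40000000000000002
weights.b_in_rg	2
weights.a_rgf_c1	0.40000000000000002
weights.b_c1_rgf	0.59999999999999998
weights.a_rge_v3	0.29999999999999999
weights.a_v3_ine	0.29999999999999999
weights.a_rgf_pff	0.80000000000000004
weights.a_rge_pfe	1.5
weights.b_in_pf	1
weights.mn	2	2	2	2	2	2	2
drive.d	1
drive.gamma_RGF	0.080000000000000002
drive.gamma_RGE	0.5
feedback.kFv	0.10000000000000001
feedback.kFl	0.14999999999999999
feedback.kEf	0.40000000000000002
feedback.eta_v	0.29999999999999999
feedback.eta_l	0.29999999999999999
feedback.eta_f	0.29999999999999999
muscles.Fmax	80	250	300	40	150	80	160
muscles.lmax	0.065000000000000002	0.070000000000000007	0.070000000000000007	0.055000000000000000	0.059999999999999998	0.095000000000000001	0.074999999999999997
muscles.l_neutral	0.84999999999999998	0.84999999999999998	0.84999999999999998	0.84999999999999998	0.84999999999999998	0.75000000000000000	0.75000000000000000
muscles.hip_dpp	2	2	0	0	0	2	0
muscles.knee_dpp	0.0	0.0	2.0	0.0	0.0	2.0	4.5
muscles.ankle_dpp	0.0	0.0	0.0	2.0	2.0	0.0	1.5
muscles.hip_sign	1	-1	0	0	0	-1	0
muscles.knee_sign	0	0	-1	0	0	1	1
muscles.ankle_sign	0	0	0	1	-1	0	-1
curves.fl_beta	1.55
curves.fl_omega	0.81000000000000005
curves.fl_rho	2.1200000000000001
curves.vmax	8
curves.fv_af	0.25
curves.fv_ecc_gain	0.80000000000000004
curves.fv_ecc_sat	2
curves.fp_k	0.02
curves.fp_c	6
curves.fp_slack	1
skeleton.g	9.8100000000000005
skeleton.trunk.m	2
skeleton.trunk.L	0.25
skeleton.trunk.com	0.71999999999999997
skeleton.trunk.I	0.014999999999999999
skeleton.thigh.m	0.25
skeleton.thigh.L	0.10000000000000001
skeleton.thigh.com	0.45000000000000001
skeleton.thigh.I	0.00025000000000000001
skeleton.crus.m	0.10000000000000001
skeleton.crus.L	0.12
skeleton.crus.com	0.45000000000000001
skeleton.crus.I	0.00013999999999999999
skeleton.foot.m	0.029999999999999999
skeleton.foot.L	0.070000000000000007
skeleton.foot.com	0.5
skeleton.foot.I	0.000020000000000000002
skeleton.L_fore	0.20999999999999999
skeleton.neutral_deg	60	90	100
skeleton.joint_damping	0.02
skeleton.joint_limits.lo_deg	30	40	40
skeleton.joint_limits.hi_deg	160	175	175
skeleton.joint_limits.k	30
skeleton.joint_limits.c	0.5
contact.k_n	10000
contact.c_n	120
contact.c_t	400
contact.v_belt	0.20000000000000001
contact.platform.height	0.02
contact.platform.k_h	500
contact.platform.c_h	30
contact.platform.k_v	3000
contact.platform.c_v	60
contact.platform.anchor_x	0
contact.platform.half_length	0.059999999999999998
sim.dt	0.040000000000000001
sim.settle	3000
sim.log_stride	25
sim.fall_hip	0.050000000000000003
sim.airborne_factor	1.5
sim.airborne_default	2
sim.cap	100
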
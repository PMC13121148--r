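feature	contrast	ref_group	cmp_group	ref_mean	cmp_mean	fc_printed	p_printed	vip_printed	fc_consistent
PGF1a-1	hc_vs_pre	HC	PV_pre	32.940	20.207	0.613	0.009	NA	TRUE
PGF1a-2	hc_vs_pre	HC	PV_pre	81.638	50.081	0.613	0.049	NA	TRUE
PGB2-1	hc_vs_pre	HC	PV_pre	39.315	27.933	0.710	0.023	NA	TRUE
LTB5	hc_vs_pre	HC	PV_pre	64.064	40.787	0.637	0.022	NA	TRUE
PGD3	hc_vs_pre	HC	PV_pre	7.929	4.303	0.543	0.018	NA	TRUE
TXB3-1	hc_vs_pre	HC	PV_pre	0.275	0.191	0.694	0.016	NA	FALSE
RVE2-2	hc_vs_pre	HC	PV_pre	0.584	0.258	0.442	0.002	NA	TRUE
RVE2-3	hc_vs_pre	HC	PV_pre	15.745	9.901	0.629	0.043	NA	TRUE
RVD1-1	hc_vs_pre	HC	PV_pre	1.604	0.699	0.436	0.030	NA	TRUE
17(R)-RVD1	hc_vs_pre	HC	PV_pre	0.482	0.204	0.424	0.011	NA	FALSE
RVD1-3	hc_vs_pre	HC	PV_pre	3.907	2.487	0.637	0.025	NA	TRUE
(+/-)19(20)-EpDPA	hc_vs_pre	HC	PV_pre	0.126	0.210	1.669	0.038	NA	FALSE
PGF1a-1	pre_vs_post	PV_pre	PV_post	20.207	31.464	1.557	0.042	NA	TRUE
PGF1a-2	pre_vs_post	PV_pre	PV_post	50.081	81.496	1.627	0.036	NA	TRUE
20-HETE	pre_vs_post	PV_pre	PV_post	23.628	6.405	0.271	0.028	NA	TRUE
TXB3-1	pre_vs_post	PV_pre	PV_post	0.191	0.450	2.351	0.005	NA	FALSE
RVE1	pre_vs_post	PV_pre	PV_post	0.177	0.282	1.593	0.014	NA	TRUE
RVD1-3	pre_vs_post	PV_pre	PV_post	2.487	1.553	0.625	0.044	NA	FALSE
17(R)-RVD1	pre_vs_post	PV_pre	PV_post	0.204	0.337	1.652	0.015	NA	TRUE
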
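feature	contrast	ref_group	cmp_group	ref_mean	cmp_mean	fc_printed	p_printed	vip_printed	fc_consistent
APO(a)	hc_vs_pre	HC	PV_pre	333483.707	732538.577	2.197	0.014	3.104	TRUE
APOC3	hc_vs_pre	HC	PV_pre	8267718.335	12197153.300	1.475	0.026	9.319	TRUE
APOL1	hc_vs_pre	HC	PV_pre	309806.898	411068.855	1.327	0.014	1.033	TRUE
S100A8	hc_vs_pre	HC	PV_pre	234871.643	406391.414	1.730	0.006	1.770	TRUE
S100A9	hc_vs_pre	HC	PV_pre	306890.030	520463.183	1.696	0.003	2.107	TRUE
LTF	hc_vs_pre	HC	PV_pre	128140.167	204707.098	1.598	0.011	1.168	TRUE
AT-III	hc_vs_pre	HC	PV_pre	17380601.980	14937635.700	0.859	0.049	8.783	TRUE
C1-INH	hc_vs_pre	HC	PV_pre	28241238.950	23257027.700	0.824	0.036	10.572	TRUE
FXI	hc_vs_pre	HC	PV_pre	332973.510	238812.859	0.717	0.014	1.130	TRUE
GPX3	hc_vs_pre	HC	PV_pre	2345529.607	1651287.010	0.704	0.002	4.141	TRUE
HGFA	hc_vs_pre	HC	PV_pre	383807.679	285944.823	0.745	0.000	1.578	TRUE
CRTAC1	hc_vs_pre	HC	PV_pre	212887.059	156573.157	0.735	0.014	1.116	TRUE
NRP-1	hc_vs_pre	HC	PV_pre	304055.111	220229.200	0.724	0.006	1.166	TRUE
IGLV1-47	pre_vs_post	PV_pre	PV_post	40415.539	69670.040	1.724	0.038	1.056	TRUE
IGHG1	pre_vs_post	PV_pre	PV_post	3305068.220	4984904.830	1.508	0.038	8.398	TRUE
TF	pre_vs_post	PV_pre	PV_post	2098069.570	2667856.860	1.272	0.008	3.700	TRUE
S100A9	pre_vs_post	PV_pre	PV_post	520463.183	367209.529	0.706	0.040	1.379	TRUE
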
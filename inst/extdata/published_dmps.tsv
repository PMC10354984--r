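gene	probe_id	gene_section	status	logfc_m	ci_lo	ci_hi	abs_mean_beta_diff	q_group	p_sex	p_age	p_gc
CYP11A1	cg23808031	Promoter/1stExon	Hypermethylated	0.195	0.090	0.301	0.041	0.016	0.51	0.82	0.0090
POR	cg10738873	5'UTR	Hypomethylated	-0.116	-0.175	-0.058	0.011	0.0092	0.69	0.26	0.22
POR	cg17115737	5'UTR	Hypomethylated	-0.099	-0.159	-0.039	0.026	0.036	0.49	0.84	0.84
POR	cg27372063	Body	Hypomethylated	-0.182	-0.286	-0.078	0.026	0.026	0.29	0.24	0.068
CYB5A	cg18274065	Promoter	Hypomethylated	-0.133	-0.196	-0.071	0.019	0.0067	0.32	0.79	0.18
HSD17B1	cg02363277	Body	Hypermethylated	0.039	0.015	0.062	0.002	0.044	0.80	0.61	0.34
HSD17B2	cg09894383	Promoter	Hypomethylated	-0.080	-0.126	-0.035	0.023	0.026	0.30	0.012	0.98
HSD17B2	cg11515282	Promoter	Hypomethylated	-0.100	-0.148	-0.052	0.023	0.0067	0.76	0.029	0.52
HSD17B2	cg20373326	Promoter	Hypomethylated	-0.135	-0.190	-0.080	0.027	0.0009	0.84	0.36	0.34
HSD17B2	cg19807685	5'UTR/1stExon	Hypomethylated	-0.124	-0.182	-0.065	0.011	0.0067	0.47	0.18	0.84
HSD17B2	cg26315602	1stExon	Hypomethylated	-0.073	-0.113	-0.034	0.010	0.016	0.76	0.93	0.66
HSD17B2	cg00365986	Body	Hypomethylated	-0.134	-0.212	-0.057	0.016	0.026	0.99	0.25	0.045
HSD17B2	cg05315365	Body	Hypomethylated	-0.170	-0.259	-0.082	0.046	0.013	0.55	0.017	0.23
HSD17B2	cg13740036	Body	Hypomethylated	-0.192	-0.287	-0.098	0.052	0.0073	0.46	0.045	0.68
HSD17B3	cg18014207	Body	Hypomethylated	-0.131	-0.204	-0.058	0.031	0.025	0.89	0.13	0.056
HSD17B6	cg21922731	5'UTR/1stExon	Hypomethylated	-0.044	-0.069	-0.018	0.010	0.026	0.44	0.87	0.68
HSD17B10	cg26323797	Promoter	Hypermethylated	0.146	0.062	0.231	0.024	0.026	0.47	0.32	0.18
HSD17B12	cg14262884	Body	Hypomethylated	-0.081	-0.131	-0.030	0.010	0.049	0.38	0.048	0.66
HSD17B12	cg21077321	Body	Hypomethylated	-0.133	-0.212	-0.055	0.025	0.031	0.86	0.081	0.68
CYP19A1	cg12009872	Body	Hypomethylated	-0.057	-0.092	-0.021	0.015	0.046	0.93	0.012	0.67
CYP19A1	cg14424631	Body	Hypomethylated	-0.093	-0.138	-0.048	0.020	0.0072	0.85	0.035	0.0027
CYP21A2	cg11675917	Promoter	Hypomethylated	-0.129	-0.199	-0.060	0.019	0.016	0.043	0.24	0.44
CYP11B2	cg14389499	Promoter	Hypomethylated	-0.100	-0.159	-0.041	0.031	0.031	0.88	0.41	0.14
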
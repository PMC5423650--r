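label	P_americana_JX402724	P_americana_KF640070	P_americana_KM577024	P_americana_KM577049	P_americana_KM577080	P_americana_KM577135	P_americana_KM577145	P_americana_KM577147	P_americana_KM577150	P_americana_KM577152	P_americana_KM577154	P_americana_KM577156	P_americana_KM577157	P_americana_KM577126	P_australasiae_AM114928	P_australasiae_KX640825	P_brunnea_AM114930	P_fuliginosa_AB126004	P_japonica_AM114929	P_japonica_JQ350708	S_lateralis_NC_030003
P_americana_JX402724		0.009	0.010	0.004	0.009	0.009	0.009	0.009	0.003	0.010	0.010	0.009	0.010	0.010	0.015	0.015	0.015	0.015	0.018	0.018	0.015
P_americana_KF640070	0.045		0.007	0.009	0.002	0.002	0.005	0.004	0.009	0.007	0.006	0.002	0.007	0.007	0.015	0.015	0.015	0.014	0.018	0.018	0.015
P_americana_KM577024	0.052	0.027		0.009	0.007	0.007	0.007	0.007	0.009	0.003	0.002	0.007	0.003	0.003	0.015	0.015	0.015	0.015	0.017	0.017	0.015
P_americana_KM577049	0.008	0.042	0.049		0.008	0.008	0.009	0.009	0.002	0.009	0.009	0.008	0.009	0.009	0.015	0.015	0.015	0.015	0.017	0.017	0.015
P_americana_KM577080	0.043	0.003	0.029	0.040		0.003	0.005	0.004	0.008	0.007	0.007	0.003	0.007	0.007	0.015	0.015	0.015	0.015	0.018	0.018	0.015
P_americana_KM577135	0.045	0.003	0.027	0.042	0.007		0.004	0.003	0.008	0.007	0.006	0.002	0.006	0.007	0.015	0.015	0.015	0.015	0.018	0.018	0.015
P_americana_KM577145	0.045	0.014	0.031	0.042	0.015	0.014		0.004	0.009	0.007	0.007	0.004	0.007	0.007	0.015	0.015	0.015	0.014	0.017	0.017	0.015
P_americana_KM577147	0.047	0.008	0.029	0.043	0.010	0.008	0.012		0.009	0.007	0.006	0.003	0.007	0.007	0.015	0.015	0.015	0.014	0.017	0.017	0.015
P_americana_KM577150	0.007	0.042	0.049	0.002	0.040	0.042	0.042	0.043		0.009	0.009	0.008	0.009	0.009	0.015	0.015	0.015	0.015	0.017	0.017	0.015
P_americana_KM577152	0.056	0.027	0.007	0.052	0.029	0.027	0.031	0.029	0.052		0.002	0.007	0.003	0.002	0.015	0.015	0.015	0.015	0.018	0.017	0.016
P_americana_KM577154	0.052	0.024	0.003	0.049	0.026	0.024	0.027	0.026	0.049	0.003		0.006	0.002	0.002	0.015	0.015	0.015	0.014	0.017	0.017	0.015
P_americana_KM577156	0.043	0.002	0.026	0.040	0.005	0.002	0.012	0.007	0.040	0.026	0.022		0.006	0.006	0.015	0.015	0.015	0.014	0.018	0.018	0.015
P_americana_KM577157	0.054	0.026	0.005	0.051	0.027	0.026	0.029	0.027	0.051	0.005	0.002	0.024		0.002	0.015	0.015	0.015	0.014	0.017	0.017	0.016
P_americana_KM577126	0.054	0.026	0.005	0.051	0.027	0.026	0.029	0.027	0.051	0.002	0.002	0.024	0.003		0.015	0.015	0.015	0.014	0.017	0.017	0.016
P_australasiae_AM114928	0.124	0.122	0.120	0.122	0.124	0.122	0.118	0.118	0.122	0.126	0.122	0.120	0.122	0.124		0.002	0.013	0.011	0.016	0.016	0.016
P_australasiae_KX640825	0.122	0.120	0.118	0.120	0.122	0.120	0.116	0.116	0.120	0.124	0.120	0.118	0.120	0.122	0.002		0.013	0.011	0.016	0.016	0.016
P_brunnea_AM114930	0.120	0.118	0.120	0.116	0.120	0.120	0.112	0.114	0.116	0.122	0.118	0.118	0.118	0.120	0.101	0.099		0.013	0.016	0.016	0.017
P_fuliginosa_AB126004	0.118	0.110	0.114	0.116	0.112	0.112	0.104	0.108	0.116	0.116	0.112	0.110	0.112	0.114	0.078	0.076	0.093		0.013	0.013	0.015
P_japonica_AM114929	0.170	0.168	0.168	0.164	0.170	0.170	0.158	0.162	0.164	0.170	0.166	0.168	0.164	0.168	0.130	0.132	0.139	0.114		0.002	0.017
P_japonica_JQ350708	0.168	0.166	0.166	0.162	0.168	0.168	0.156	0.160	0.162	0.168	0.164	0.166	0.162	0.166	0.128	0.130	0.137	0.112	0.002		0.017
S_lateralis_NC_030003	0.126	0.127	0.133	0.126	0.131	0.129	0.129	0.126	0.126	0.141	0.137	0.127	0.139	0.139	0.130	0.128	0.163	0.130	0.158	0.156
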
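gene	pattern	q_value	mean_WM	mean_MGUS	mean_CTRL	fc_WM_MGUS	p_WM_MGUS	fc_MGUS_CTRL	p_MGUS_CTRL	fc_WM_CTRL	p_WM_CTRL
TJP1	p2	0.0005	3.62	5.02	6.24	-2.65	0.002	-2.33	0.013	-6.18	0.0000003
ESRP1	p2	0.002	4.44	5.4	6.44	-1.94	0.002	-2.07	0.008	-4.02	0.000005
FGF2	p2	0.0021	2.25	2.45	3.26	-1.15	0.072	-1.75	0.005	-2.01	0.000822
SEPT10	p2	0.0082	3.93	5.02	6.02	-2.14	0.004	-1.99	0.025	-4.26	0.000007
GREB1	p3	0.0092	1.92	1.75	3.46	1.12	0.005	-3.28	0.005	-2.92	0.013437
PERP	p2	0.0097	3.39	4.28	5.51	-1.85	0.03	-2.35	0.002	-4.4	0.000000002
NFIB	p2	0.0134	2.46	3.38	4.06	-1.9	0.022	-1.59	0.138	-3.04	0.000078
CALCRL	p2	0.0164	3.05	3.87	4.36	-1.77	0.008	-1.41	0.171	-2.48	0.000142
PPARGC1A	p2	0.0191	3.32	4.49	4.49	-2.24	0.004	-1	0.993	-2.25	0.000901
TUBB2B	p2	0.0225	3.26	3.31	4.85	-1.04	0.729	-2.92	0.006	-3.03	0.0065
PLA2G2D	p2	0.0276	4.85	5.6	6.62	-1.69	0.019	-2.02	0.003	-3.41	0.0000004
PARD3	p2	0.0279	5.23	5.95	6.56	-1.65	0.005	-1.52	0.071	-2.52	0.000226
OVOL1	p2	0.0293	5.49	6.03	6.54	-1.46	0.016	-1.42	0.059	-2.07	0.000058
TTLL7	p2	0.0341	2.92	3.18	4.07	-1.2	0.175	-1.86	0.011	-2.22	0.001204
GBA3	p4	0.041	3.43	5.1	4.58	-3.2	0.004	1.44	0.316	-2.22	0.001208
MYO5B	p2	0.0422	5.03	5.66	6.37	-1.55	0.025	-1.63	0.043	-2.52	0.000136
SYNM	p2	0.0426	4.84	5.81	5.91	-1.97	0.003	-1.07	0.75	-2.11	0.000054
KIAA1804	p2	0.0428	3.92	4.28	5.28	-1.29	0.216	-1.99	0.003	-2.57	0.0000005
NRG3	p4	0.043	3.01	4.05	4.03	-2.06	0.002	1.01	0.959	-2.03	0.007143
KCTD1	p2	0.0434	5.27	5.77	6.35	-1.41	0.024	-1.5	0.018	-2.11	0.000012
CNTN1	p2	0.0435	2.56	3.03	3.39	-1.39	0.011	-1.29	0.163	-1.79	0.00149
LAPTM4B	p2	0.0437	4.71	5.27	6.49	-1.48	0.086	-2.32	0.001	-3.42	0.000001
CADPS2	p2	0.0438	5.47	6.87	8.12	-2.63	0.011	-2.38	0.014	-6.26	0.0000005
ARHGAP32	p2	0.0451	4.02	4.85	5.4	-1.77	0.002	-1.47	0.061	-2.61	0.000052
GPR125	p2	0.0453	3.58	4.05	4.93	-1.38	0.031	-1.84	0.012	-2.55	0.000346
UCHL1	p2	0.0454	5.24	5.86	6.52	-1.54	0.065	-1.58	0.051	-2.42	0.000002
MARC2	p2	0.0461	4.8	6.18	6.46	-2.59	0.001	-1.22	0.433	-3.17	0.000017
TTLL7	p2	0.047	4.61	5.45	6.27	-1.79	0.03	-1.76	0.055	-3.15	0.00004
MYLK	p2	0.0486	6.13	6.96	7.53	-1.78	0.007	-1.49	0.072	-2.64	0.000028
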
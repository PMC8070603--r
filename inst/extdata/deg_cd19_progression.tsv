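gene	pattern	q_value	mean_WM	mean_MGUS	mean_CTRL	fc_WM_MGUS	p_WM_MGUS	fc_MGUS_CTRL	p_MGUS_CTRL	fc_WM_CTRL	p_WM_CTRL
HIST1H1B	p2	0.009	6.41	7.18	8.85	-1.71	0.118	-3.18	0.022	-5.45	0.000477
EZH2	p2	0.037	7.25	7.37	8.79	-1.09	0.733	-2.67	0.002	-2.91	0.000034
CHEK1	p2	0.040	4.81	5.14	6.49	-1.26	0.411	-2.55	0.004	-3.22	0.000024
LEF1	p2	0.041	5.24	5.82	7.19	-1.5	0.19	-2.58	0.01	-3.86	0.000136
ADAM23	p2	0.045	4.12	4.84	6.15	-1.64	0.137	-2.48	0.011	-4.07	0.000032
RASGRP3	p3	0.045	4.57	4.47	5.60	1.07	0.687	-2.19	0.001	-2.05	0.002118
ADRB2	p1	0.047	7.33	6.98	6.13	1.28	0.226	1.8	0.005	2.31	0.000003
PIK3AP1	p2	0.047	10.15	10.24	10.84	-1.06	0.565	-1.51	0.002	-1.61	0.000206
CDHR3	p2	0.048	4.82	5.31	6.29	-1.4	0.142	-1.98	0.028	-2.77	0.001467
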
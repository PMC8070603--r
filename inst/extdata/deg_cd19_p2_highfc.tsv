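gene	pattern	q_value	mean_WM	mean_MGUS	mean_CTRL	fc_WM_MGUS	p_WM_MGUS	fc_MGUS_CTRL	p_MGUS_CTRL	fc_WM_CTRL	p_WM_CTRL
HIST1H1B	p2	0.0093	6.41	7.18	8.85	-1.71	0.118	-3.18	0.022	-5.45	0.000477
ADARB1	p2	0.0127	5.98	7.11	8.21	-2.19	0.011	-2.16	0.015	-4.72	0.000004
ADAM28	p2	0.0171	5.71	6.76	7.44	-2.08	0.008	-1.6	0.154	-3.33	0.000568
APBB2	p2	0.0248	4.61	5.88	7.07	-2.42	0.024	-2.27	0.034	-5.5	0.000009
EZH2	p2	0.0374	7.25	7.37	8.79	-1.09	0.733	-2.67	0.002	-2.91	0.000034
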
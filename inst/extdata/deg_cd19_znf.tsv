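gene	pattern	q_value	mean_WM	mean_MGUS	mean_CTRL	fc_WM_MGUS	p_WM_MGUS	fc_MGUS_CTRL	p_MGUS_CTRL	fc_WM_CTRL	p_WM_CTRL
ZNF804A	p1	0.0021	8.36	6.01	5.12	5.12	0.00036	1.85	0.184	9.48	0.000003
ZNF215	p1	0.0273	3.44	2.85	2.60	1.51	0.000202	1.19	0.14	1.79	0.000784
IKZF2	p2	0.0453	6.49	7.72	8.83	-2.33	0.025399	-2.16	0.026	-5.05	0.000026
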
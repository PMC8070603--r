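gene	pattern_cd19	pattern_cd138	fc_WM_MGUS_cd19	fc_MGUS_CTRL_cd19	fc_WM_CTRL_cd19	fc_WM_MGUS_cd138	fc_MGUS_CTRL_cd138	fc_WM_CTRL_cd138
ARHGAP32	p2	p2	-2.52	-1.55	-3.9	-1.77	-1.47	-2.61
MARC2	p2	p2	-2.47	-1.51	-3.72	-2.59	-1.22	-3.17
LAPTM4B	p2	p2	-1.76	-1.57	-2.76	-1.48	-2.32	-3.42
PLA2G2D	p2	p2	-1.5	-1.1	-1.65	-1.69	-2.02	-3.41
KIAA1804	p2	p2	-1.36	-2.02	-2.76	-1.29	-1.99	-2.57
MYLK	p2	p2	-2.04	-1.28	-2.61	-1.78	-1.49	-2.64
SYNM	p2	p2	-1.59	-1.15	-1.84	-1.97	-1.07	-2.11
TJP1	p4	p2	-1.33	1.09	-1.22	-2.65	-2.33	-6.18
GBA3	p4	p2	-1.87	1.51	-1.24	-3.54	1.44	-2.46
NFIB	p4	p2	-1.77	1.12	-1.59	-1.9	-1.59	-3.04
PPARGC1A	p4	p2	-1.27	1.15	-1.1	-2.24	-1	-2.25
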
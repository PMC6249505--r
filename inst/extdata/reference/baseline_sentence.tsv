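row	positive_count	pct_positive	precision	recall	f_score	specificity
A1a	120	0.021	0.70	0.52	0.59	0.99
A1b	91	0.016	0.50	0.42	0.45	0.99
A1c	35	0.006	0.16	0.17	0.17	0.99
A1d	160	0.029	0.54	0.14	0.22	1.00
A2a	388	0.069	0.71	0.39	0.50	1.00
A2b	321	0.057	0.69	0.37	0.48	0.99
A2c	120	0.021	0.54	0.47	0.51	0.99
A2d	62	0.011	0.34	0.19	0.25	1.00
A3a	64	0.011	0.20	0.09	0.13	1.00
A3b	123	0.022	0.81	0.47	0.59	1.00
A3c	66	0.012	0.70	0.32	0.44	1.00
A3d	27	0.005	0.27	0.30	0.28	1.00
Microaverage	1577	0.024	0.60	0.35	0.45	0.99
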
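class	radius	epsilon	gamma	hct_scale
C	2.00	0.110	0.015	0.72
CH1	2.27	0.090	0.015	0.72
CH2	2.22	0.120	0.015	0.72
CH3	2.17	0.180	0.015	0.72
CR	2.10	0.120	0.015	0.72
NH	1.85	0.200	0.000	0.79
N	1.85	0.200	0.000	0.79
NC	1.85	0.200	0.000	0.79
O	1.70	0.120	0.000	0.85
OC	1.70	0.120	0.000	0.85
OH	1.77	0.150	0.000	0.85
S	2.00	0.450	0.010	0.96
H	0.60	0.046	0.000	0.85
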
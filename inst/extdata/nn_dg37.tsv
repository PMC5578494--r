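category	key	dg
stack	AA/UU	-0.93
stack	UA/AU	-1.33
stack	CA/GU	-2.11
stack	GA/CU	-2.35
stack	GA/UU	-1.27
stack	UA/GU	-1
stack	AU/UA	-1.1
stack	UU/AA	-0.93
stack	CU/GA	-2.08
stack	GU/CA	-2.24
stack	GU/UA	-1.36
stack	UU/GA	-0.55
stack	AC/UG	-2.24
stack	UC/AG	-2.35
stack	CC/GG	-3.26
stack	GC/CG	-3.42
stack	GC/UG	-2.51
stack	UC/GG	-1.53
stack	AG/UC	-2.08
stack	UG/AC	-2.11
stack	CG/GC	-2.36
stack	GG/CC	-3.26
stack	GG/UC	-2.11
stack	UG/GC	-1.41
stack	AG/UU	-0.55
stack	UG/AU	-1
stack	CG/GU	-1.41
stack	GG/CU	-1.53
stack	GG/UU	-0.5
stack	UG/GU	0.3
stack	AU/UG	-1.36
stack	UU/AG	-1.27
stack	CU/GG	-2.11
stack	GU/CG	-2.51
stack	GU/UG	1.29
stack	UU/GG	-0.5
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4
bulge	6	4.4
bulge	7	4.57
bulge	8	4.71
bulge	9	4.84
bulge	10	4.95
bulge	11	5.05
bulge	12	5.15
bulge	13	5.23
bulge	14	5.31
bulge	15	5.39
bulge	16	5.46
bulge	17	5.52
bulge	18	5.58
bulge	19	5.64
bulge	20	5.7
bulge	21	5.75
bulge	22	5.8
bulge	23	5.85
bulge	24	5.9
bulge	25	5.94
bulge	26	5.98
bulge	27	6.02
bulge	28	6.06
bulge	29	6.1
bulge	30	6.14
interior	2	1.2
interior	3	1.6
interior	4	1.7
interior	5	1.8
interior	6	2
interior	7	2.17
interior	8	2.31
interior	9	2.44
interior	10	2.55
interior	11	2.65
interior	12	2.75
interior	13	2.83
interior	14	2.91
interior	15	2.99
interior	16	3.06
interior	17	3.12
interior	18	3.18
interior	19	3.24
interior	20	3.3
interior	21	3.35
interior	22	3.4
interior	23	3.45
interior	24	3.5
interior	25	3.54
interior	26	3.58
interior	27	3.62
interior	28	3.66
interior	29	3.7
interior	30	3.74
misc	duplex_init	4.09
misc	terminal_au	0.45
misc	asym_per_nt	0.6
misc	asym_cap	3
misc	max_loop	15
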
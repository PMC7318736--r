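chrom	subgenome	mm_len_cm	gr_len_mb	n_markers	n_snps	mm_n_segments	gr_n_segments	mm_cov_cm	gr_cov_mb
A01	At	115.34	117.71	14	361606	19	91	82.08	108.57
A02	At	147.16	108.05	18	604209	19	40	76.08	105.69
A03	At	161.99	113.01	19	596783	10	53	137.58	104.41
A04	At	140.78	85.11	18	466455	20	41	123.75	82.41
A05	At	207.21	109.37	21	524501	20	53	169.42	85.68
A06	At	172.09	124.01	19	662304	16	46	120.19	114.98
A07	At	115.52	97.74	16	528301	14	34	29.42	39.40
A08	At	141.97	122.33	20	673976	13	60	63.98	120.00
A09	At	187.02	82.06	21	432266	23	39	124.75	78.94
A10	At	185.70	114.80	21	616965	16	22	163.96	100.14
A11	At	239.20	123.16	29	665538	23	33	193.20	121.58
A12	At	222.31	107.62	26	600282	29	42	202.90	100.35
A13	At	213.83	108.33	23	611835	14	27	171.66	102.50
D01	Dt	178.95	63.18	22	331752	17	27	124.09	53.84
D02	Dt	102.25	69.81	12	405754	10	14	85.99	64.76
D03	Dt	145.67	52.68	17	302944	20	27	132.24	52.67
D04	Dt	167.36	56.41	20	299802	10	17	145.07	48.92
D05	Dt	243.38	62.90	28	295927	22	35	196.42	51.82
D06	Dt	153.96	66.84	18	359172	29	36	131.23	61.67
D07	Dt	152.94	59.23	18	308614	14	126	129.79	56.28
D08	Dt	145.99	69.01	16	360933	21	116	145.99	67.78
D09	Dt	174.52	52.80	20	290463	25	29	158.55	44.98
D10	Dt	160.88	67.98	17	378681	14	36	126.42	62.95
D11	Dt	265.89	72.91	32	321124	30	62	209.45	32.85
D12	Dt	123.72	62.67	14	305337	15	73	88.12	30.38
D13	Dt	136.87	63.32	16	348137	17	32	120.31	29.40
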
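Plan	ProbeID	Chr	ProbePos	Gene	SNP	Pos	A1	Freq	P_GWAS	P_mQTL	b_SMR	SE_SMR	P_SMR	P_HEIDI	N_HEIDI	Current	Previous	Region
2	cg05206559	19q13.32	45913997	NANOS2	rs66529687	45914171	A	0.133	1.83E-04	2.84E-41	0.723	0.125	7.67E-09	3.28E-01	20	G	G	G
2	cg25673584	19q13.32	45914293	NANOS2	rs66529687	45914171	A	0.133	1.83E-04	4.40E-30	0.849	0.152	2.45E-08	1.23E-01	20	G	G	G
2	cg14192299	19q13.32	45914381	NANOS2	rs66529687	45914171	A	0.133	1.83E-04	6.71E-42	0.718	0.124	7.30E-09	1.08E-01	20	G	G	G
2	cg19702802	19q13.32	45914471	NANOS2	rs66529687	45914171	A	0.133	1.83E-04	3.22E-39	0.743	0.129	9.10E-09	1.03E-01	20	G	G	G
3	cg10218546	6p21.32	32762046	HLA-DQB2	rs7768538	32762044	C	0.426	6.15E-05	1.30E-126	-0.304	0.060	3.27E-07	6.43E-02	20	S	G	G
4	cg23395749	5q35.3	177557245	FAM193B	rs1001530	177558514	G	0.046	3.36E-04	2.55E-26	-0.484	0.088	3.08E-08	8.77E-02	5	N	S	S
5	cg08631357	5q32	150209647	SLC6A7	rs10076748	150209303	A	0.107	1.77E-03	1.54E-193	0.288	0.056	3.18E-07	2.02E-01	20	N	N	G
5	cg23891049	7q33	134679117	BPGM	rs73441994	134679118	A	0.021	4.26E-02	1.18E-229	-0.156	0.030	1.70E-07	6.07E-01	4	N	S	S
5	cg24635736	10q26.13	122979534	PSTK	rs2421140	123027854	A	0.029	8.09E-03	2.67E-77	-0.346	0.060	6.12E-09	7.16E-01	8	N	N	N
5	cg05360847	11q13.4	71576873	KRTAP5-11	rs11827208	71578103	T	0.020	1.70E-03	3.47E-13	-0.942	0.159	3.50E-09	2.02E-01	4	N	N	S
5	cg17632299	13q14.3	52738831	LECT1	rs4885947	52735009	C	0.037	1.23E-03	7.51E-54	0.592	0.085	2.67E-12	1.34E-01	20	N	G	G
5	cg09557313	13q14.3	52739039	LECT1	rs4885947	52735009	C	0.037	1.23E-03	1.46E-40	0.675	0.100	1.37E-11	1.02E-01	20	N	G	G
5	cg09397293	16p13.3	2005032	ZNF598	rs72766639	2005819	A	0.174	1.69E-04	5.78E-51	0.688	0.116	3.06E-09	2.85E-01	20	N	S	G
5	cg26804891	16p13.3	2005241	ZNF598	rs11248905	1999727	T	0.181	4.88E-05	3.56E-98	0.539	0.080	1.62E-11	7.60E-02	20	N	S	G
5	cg08576185	16p13.3	2005683	ZNF598	rs72766639	2005819	A	0.174	1.69E-04	4.06E-44	0.740	0.126	4.76E-09	3.59E-01	20	N	S	G
5	cg10470208	16p13.3	2008700	ZNF598	rs1058474	1998795	T	0.181	6.82E-05	6.56E-19	1.112	0.209	1.02E-07	7.58E-02	14	N	S	G
5	cg06998361	16q21	58110599	C16orf80	rs10445026	58109349	G	0.069	5.00E-04	5.61E-97	-0.442	0.069	1.35E-10	2.53E-01	20	N	S	S
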
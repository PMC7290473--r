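Plan	ProbeID	Chr	ProbePos	Gene	SNP	Pos	A1	Freq	P_GWAS	P_mQTL	b_SMR	SE_SMR	P_SMR	P_HEIDI	N_HEIDI	Current	Previous	Region
2	cg05206559	19q13.32	45913997	NANOS2	rs66529687	45914171	G	0.867	1.83E-04	5.86E-298	0.272	0.043	2.96E-10	8.50E-01	19	G	G	G
3	cg04322111	6p21.32	32761987	HLA-DQB2	rs7768538	32762044	A	0.574	6.15E-05	0	-0.201	0.039	2.21E-07	8.61E-02	20	S	G	G
3	cg10218546	6p21.32	32762046	HLA-DQB2	rs7768538	32762044	A	0.574	6.15E-05	0	-0.198	0.038	2.18E-07	8.32E-02	20	S	G	G
4	cg23395749	5q35.3	177557245	FAM193B	rs1001530	177558514	A	0.954	3.36E-04	2.34E-15	-0.791	0.157	5.17E-07	1.01E-01	5	N	S	S
5	cg08631357	5q32	150209647	SLC6A7	rs10076748	150209303	C	0.893	1.77E-03	2.82E-295	0.230	0.045	2.76E-07	2.24E-01	18	N	N	G
5	cg10308629	7q33	134670051	BPGM	rs73439998	134663724	C	0.979	3.01E-02	9.28E-48	-0.520	0.101	2.88E-07	2.57E-01	3	N	S	S
5	cg24635736	10q26.13	122979534	PSTK	rs13328826	122992107	A	0.970	6.26E-03	2.48E-20	-0.374	0.072	1.68E-07	8.24E-01	3	N	N	N
5	cg15567360	11q13.4	71611653	KRTAP5-11	rs11827208	71578103	C	0.980	1.70E-03	9.66E-10	-0.679	0.130	1.67E-07	3.71E-01	3	N	N	S
5	cg09557313	13q14.3	52739039	LECT1	rs4885961	52755200	C	0.960	4.63E-03	6.93E-31	0.547	0.103	1.06E-07	5.67E-01	7	N	G	G
5	cg07011318	16p13.3	2004943	ZNF598	rs72766639	2005819	G	0.826	1.69E-04	0	0.291	0.046	1.96E-10	1.12E-01	17	N	S	G
5	cg09397293	16p13.3	2005032	ZNF598	rs72766639	2005819	G	0.826	1.69E-04	0	0.282	0.044	1.86E-10	1.13E-01	18	N	S	G
5	cg05211189	16p13.3	2005402	ZNF598	rs11542302	1986934	T	0.819	7.26E-05	0	0.283	0.043	7.47E-11	1.01E-01	18	N	S	G
5	cg08576185	16p13.3	2005683	ZNF598	rs72766639	2005819	G	0.826	1.69E-04	0	0.295	0.046	2.00E-10	9.02E-02	16	N	S	G
5	cg06998361	16q21	58110599	C16orf80	rs74019790	58107923	T	0.931	5.00E-04	4.77E-20	-0.591	0.109	5.49E-08	6.81E-01	11	N	S	S
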
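Tissue	ProbeID	Chr	ProbePos	Gene	SNP	Pos	A1	Freq	P_GWAS	P_mQTL	b_SMR	SE_SMR	P_SMR	P_HEIDI	N_HEIDI
blood	cg03063511	2p13.1	73930386	DGUOK	rs6737156	73932607	C	0.036	5.62E-03	2.71E-227	-0.247	0.041	2.74E-09	1.09E-01	11
blood	cg02850715	11q24.3	130159317	ST14	rs34008994	130165703	T	0.096	1.55E-04	1.21E-26	-0.812	0.138	4.14E-09	7.87E-01	20
blood	cg21029769	11q24.3	130159620	ST14	rs34008994	130165703	T	0.096	1.55E-04	4.09E-18	-1.006	0.184	4.58E-08	9.16E-01	20
blood	cg06998361	16q21	58110599	C16orf80	rs10445026	58109349	G	0.069	5.00E-04	5.61E-97	-0.442	0.069	1.35E-10	2.53E-01	20
brain	cg11003133	1q23.1	159076601	AIM2	rs16841642	159077008	G	0.952	5.30E-03	6.30E-82	-0.312	0.062	4.62E-07	3.40E-01	18
brain	cg06998361	16q21	58110599	C16orf80	rs74019790	58107923	T	0.931	5.00E-04	4.77E-20	-0.591	0.109	5.49E-08	6.81E-01	11
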
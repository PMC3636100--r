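# Independent pleiotropic loci with conjunction FDR (SCZ & BD) < 0.05,
# from a published PGC-based cross-disorder conjunction FDR analysis (r2 < 0.2 pruning).
# conjfdr is the maximum of the two conditional FDR estimates; z-scores signed by the A1 (minor) allele.
locus	snp	gene	chr	a1	a2	conjfdr	z_bd	z_scz
1	rs2252865	RERE	1p36.23	T	C	0.030	3.696	3.494
2	rs4650608	IFI44	1p31.1	T	C	0.043	3.289	3.711
4	rs11205362	PRP3	1q21.1	G	A	0.033	3.404	3.262
8	rs9834970	TRANK1	3p22.2	C	T	0.027	3.470	3.965
9	rs4687657	ITIH4	3p21.1	G	T	0.028	3.787	3.781
11	rs3134942	NOTCH4	6p21.3	G	T	0.048	3.251	3.571
15	rs3757440	MAD1L1	7p22	A	G	0.031	3.490	3.425
20	rs10883757	TRIM8	10q24.3	C	T	0.040	3.261	3.046
22	rs1006737	CACNA1C	12p13.3	A	G	0.022	4.553	4.137
26	rs961196	TTC7B	14q32.11	C	T	0.044	3.618	2.960
28	rs12708772	SHISA9	16p13.12	C	T	0.044	3.294	2.955
31	rs1800359	ZNF276	16q24.3	A	G	0.035	3.329	3.165
33	rs159788	BC039673	20p13	G	A	0.034	3.411	-3.232
35	rs381523	PPM1F	22q11.22	A	G	0.045	3.220	3.166
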
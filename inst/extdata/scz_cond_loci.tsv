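# Independent schizophrenia (SCZ) loci with conditional FDR given bipolar disorder (SCZ|BD) < 0.05,
# from a published PGC-based cross-disorder conditional FDR analysis (r2 < 0.2 pruning).
# fdr_scz is the unconditional FDR estimate; fdr_scz_bd the conditional estimate.
locus	snp	gene	chr	pval_scz	fdr_scz	fdr_scz_bd
1	rs2252865	RERE	1p36.23	4.76E-04	0.377	0.030
2	rs11579756	KIAA1026	1p36.21	1.17E-04	0.203	0.037
3	rs4949526	BC042538	1p35.2	1.11E-04	0.181	0.035
4	rs4650608	IFI44	1p31.1	2.06E-04	0.257	0.028
5	rs4907103	LPAR3	1p22.3	9.77E-05	0.181	0.039
6	rs1625579	AK094607	1p21.3	3.76E-06	0.065	0.011
7	rs11205362	PRP3	1q21.1	1.11E-03	0.489	0.033
8	rs10495658	RAD51AP2	2p24.2	3.99E-05	0.115	0.044
9	rs813592	GCKR	2p23	2.71E-05	0.095	0.014
10	rs10189138	VRK2	2p16.1	1.42E-04	0.229	0.038
11	rs11692886	SH3RF3	2q13	1.05E-04	0.181	0.035
12	rs6435387	KIF5C	2q23.1	4.28E-05	0.115	0.020
13	rs17180327	CWC22	2q31.3	1.29E-05	0.080	0.038
14	rs17662626	PCGEM1	2q32	7.79E-05	0.161	0.030
15	rs2675968	C2orf82	2q37.1	5.64E-05	0.143	0.021
16	rs4663627	AGAP1	2q37	1.31E-04	0.203	0.033
17	rs13072940	TRANK1	3p22.2	1.27E-05	0.080	0.013
18	rs4687657	ITIH4	3p21.1	1.56E-04	0.229	0.028
19	rs11130874	PTPRG	3p21-p14	9.45E-06	0.077	0.030
20	rs9838229	DKFZp434A128	3q26.33	2.89E-05	0.104	0.045
21	rs13150700	SORBS2	4q35.1	2.77E-04	0.286	0.048
22	rs9379780	SCGN	6p22.3-p22.1	3.78E-06	0.065	0.024
22	rs198829	HIST1H2BC	6p22.1	2.18E-05	0.088	0.027
23	rs7749823	HIST1H2BD	6p21.3	1.32E-07	0.014	0.005
23	rs17693963	BC035101	6p22.1	1.87E-07	0.022	0.001
23	rs13190937	ZSCAN23	6p22.1	1.23E-04	0.203	0.033
23	rs3130893	ZNF311	6p22.1	3.83E-06	0.065	0.006
23	rs2523722	TRIM26	6p21.32-p22.1	2.54E-07	0.025	0.001
23	rs2596565	MICA	6p21.33	9.33E-06	0.077	0.009
23	rs2284178	HCP5	6p21.3	3.31E-04	0.316	0.036
23	rs805294	LY6G6C	6p21.33	1.11E-04	0.181	0.039
23	rs9268858	HLA-DRA	6p21.3	1.66E-05	0.084	0.041
23	rs9268862	HLA-DRA	6p21.3	6.21E-07	0.037	0.002
23	rs502771	HLA-DRB5	6p21.3	2.97E-05	0.104	0.039
23	rs9276601	HLA-DQB2	6p21	3.07E-05	0.104	0.015
23	rs7383287	HLA-DOB	6p21.3	2.71E-05	0.095	0.019
23	rs1480380	HLA-DMA	6p21.3	1.06E-05	0.077	0.010
24	rs9462875	CUL9	6p21.1	1.61E-04	0.229	0.036
25	rs7787274	FTSJ2	7p22	3.27E-04	0.316	0.028
26	rs12543276	AK055863	8p23.1	1.38E-04	0.203	0.046
27	rs7004633	MMP16	8q21.3	1.70E-07	0.018	0.005
28	rs2254884	ABCA1	9q31.1	1.17E-04	0.203	0.032
29	rs6602217	AK094154	10p14	2.29E-05	0.095	0.015
30	rs7084499	ANK3	10q21	1.74E-04	0.229	0.040
31	rs2153522	ANK3	10q21	7.92E-04	0.449	0.046
32	rs7895695	RRP12	10q24.1	3.57E-05	0.115	0.018
33	rs2298278	SUFU	10q24.32	1.24E-03	0.527	0.037
33	rs10883817	CNNM2	10q24.32	1.13E-05	0.080	0.020
33	rs11191580	NT5C2	10q24.32	1.71E-06	0.049	0.005
34	rs4356203	PIK3C2A	11p15.5-p14	5.48E-05	0.128	0.029
35	rs676318	LRP5	11q13.4	1.41E-05	0.080	0.023
36	rs6591348	GAL	11q13.3	1.16E-05	0.080	0.027
37	rs17126243	LOC399959	11q24.1	1.29E-05	0.080	0.027
38	rs11222395	SNX19	11q25	1.36E-04	0.203	0.032
39	rs7106715	IGSF9B	11q25	6.52E-05	0.143	0.039
40	rs7972947	CACNA1C	12p13.3	5.32E-07	0.035	0.013
41	rs1006737	CACNA1C	12p13.3	3.52E-05	0.104	0.022
42	rs4517638	DAOA	13q34	1.10E-05	0.077	0.015
43	rs961196	TTC7B	14q32.11	3.07E-03	0.662	0.044
44	rs1502404	TMCO5A	15q14	1.04E-03	0.489	0.040
45	rs724729	C15orf54	15q14	4.70E-05	0.128	0.038
46	rs1869901	PLCB2	15q15	2.03E-04	0.257	0.039
47	rs2414718	BC033962	15q22.2	4.59E-05	0.128	0.025
48	rs1051168	NMB	15q22	1.27E-04	0.203	0.033
49	rs1078163	NTRK3	15q25	2.67E-05	0.095	0.017
50	rs2304634	DNAJA3	16p13.3	7.90E-05	0.161	0.026
51	rs12708772	SHISA9	16p13.12	3.12E-03	0.662	0.044
52	rs4785714	ZNF276	16q24.3	1.34E-03	0.527	0.034
53	rs12966547	AK093940	18q21.2	6.23E-06	0.071	0.019
54	rs159788	BC039673	20p13	1.23E-03	0.527	0.034
55	rs381523	PPM1F	22q11.22	1.55E-03	0.560	0.038
56	rs9621795	LARGE	22q12.3	1.66E-05	0.084	0.041
57	rs5758209	EP300	22q13.2	5.06E-06	0.068	0.031
58	rs28729663	RPL23AP82	22q13.33	1.82E-04	0.257	0.041
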
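# Independent bipolar disorder (BD) loci with conditional FDR given schizophrenia (BD|SCZ) < 0.05,
# from a published PGC-based cross-disorder conditional FDR analysis (r2 < 0.2 pruning).
# fdr_bd is the unconditional FDR estimate; fdr_bd_scz the conditional estimate.
locus	snp	gene	chr	pval_bd	fdr_bd	fdr_bd_scz
1	rs2252865	RERE	1p36.23	2.19E-04	0.44657	0.01306
2	rs4650608	IFI44	1p31.1	1.00E-03	0.64629	0.04250
3	rs10776799	NGF	1p13.1	9.68E-06	0.17368	0.02579
4	rs7521783	PLEKHO1	1q21.2	5.58E-04	0.57626	0.02503
5	rs573140	SIPA1L2	1q42.2	6.58E-06	0.15946	0.03009
6	rs3911862	FLJ16124	2p14	5.65E-05	0.26909	0.04864
7	rs2271893	LMAN2L	2q11.2	1.85E-05	0.18928	0.00960
8	rs9834970	TRANK1	3p22.2	5.20E-04	0.57626	0.02711
9	rs2535629	ITIH3	3p21.1	1.29E-05	0.17896	0.00279
10	rs2902101	ODZ2	5q34	1.04E-04	0.33589	0.03570
11	rs3134942	NOTCH4	6p21.3	1.15E-03	0.66028	0.04844
12	rs9371601	SYNE1	6q25	1.10E-06	0.06351	0.02196
13	rs3823198	RPS6KA2	6q27	4.16E-05	0.22281	0.01779
14	rs4332037	MAD1	7p22	3.97E-05	0.22281	0.02918
15	rs6461233	MAD1L1	7p22	5.19E-04	0.57626	0.02711
16	rs10277665	THSD7A	7p21.3	5.42E-05	0.24328	0.01641
17	rs6982836	AX747593	8q13.2	5.64E-05	0.26909	0.04168
18	rs7083127	CACNB2	10p12	1.40E-04	0.37364	0.02191
19	rs10994359	ANK3	10q21	8.12E-10	0.00115	0.00001
20	rs10883757	TRIM8	10q24.3	1.11E-03	0.64629	0.03991
21	rs17138230	ODZ4	11q14.1	1.43E-05	0.18382	0.03822
22	rs2239037	CACNA1C	12p13.3	9.06E-04	0.64629	0.03928
22	rs10774037	CACNA1C	12p13.3	2.42E-07	0.01859	0.00161
23	rs7296288	DHH	12q13.1	2.88E-05	0.20749	0.02777
24	rs12427050	NEDD1	12q23.1	5.00E-04	0.57626	0.04728
25	rs4390476	SLITRK1	13q31.1	2.03E-04	0.44657	0.03843
26	rs961196	TTC7B	14q32.11	2.96E-04	0.50926	0.01872
27	rs11160562	EML1	14q32	6.93E-04	0.60769	0.03496
28	rs12708772	SHISA9	16p13.12	9.89E-04	0.64629	0.04219
29	rs11863156	AKTIP	16q12.2	7.86E-05	0.30029	0.00865
30	rs1424003	CDH11	16q21	5.54E-05	0.24328	0.01641
31	rs3809646	C16orf7	16q24	5.76E-04	0.60769	0.03171
32	rs281393	RASIP1	19q13.33	5.99E-05	0.26909	0.01293
33	rs159788	BC039673	20p13	6.48E-04	0.60769	0.03080
34	rs3746972	ITGB2	21q22.3	1.42E-04	0.41109	0.04369
35	rs381523	PPM1F	22q11.22	1.28E-03	0.66028	0.04536
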
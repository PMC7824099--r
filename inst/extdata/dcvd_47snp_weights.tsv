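rsid	gene	band	chrom	nonrisk_allele	risk_allele	raf_case	raf_control	or	p
rs4621553	KCNN2	5q22.2	5	A	G	0.09	0.05	1.05	0.002
rs9818870	MRAS	3q22.3	3	C	T	0.03	0.01	1.08	0.011
rs599839	CELSR2_PSRC1	1p13.3	1	A	G	0.09	0.06	1.04	0.015
rs16893526	IBTK	6q14.1	6	G	A	0.15	0.11	1.03	0.017
rs879324	ZFHX3	16q22.3	16	A	G	0.67	0.62	1.02	0.022
rs1333042	CDKN2B	9p21.3	9	A	G	0.71	0.65	1.02	0.025
rs11610422	MREGP1	12p11.21	12	A	G	0.07	0.05	1.04	0.027
rs17035270	LOC100288146	4q24	4	C	T	0.99	0.04	1.04	0.028
rs16851055	SPSB4	3q23	3	G	A	0.23	0.18	1.02	0.036
rs2814993	ILRUN	6p21.31	6	G	A	0.03	0.01	1.07	0.037
rs7865618	MTAP	9p21.3	9	G	A	0.90	0.86	1.02	0.037
rs12801636	PCNXL3	11q13.1	11	A	G	0.56	0.49	1.02	0.038
rs6706785	HDAC4	2q37.3	2	G	T	0.32	0.27	1.02	0.040
rs17006292	TFCP2L1	2q14.2	2	C	A	0.04	0.03	1.05	0.043
rs3782889	MYL2	12q24.11	12	G	A	0.88	0.83	1.02	0.046
rs4538911	MCPH1	8p23.2	8	C	G	0.13	0.06	1.08	5.0e-7
rs9982069	LOC100505973	21q21.1	21	G	A	0.49	0.38	1.04	9.1e-7
rs17465734	CDH11	16q21	16	T	A	0.05	0.01	1.14	8.0e-6
rs7946015	CD82	11p11.2	11	A	T	0.26	0.17	1.04	8.2e-6
rs5768165	FAM19A5	22q13.31	22	G	T	0.11	0.05	1.07	1.3e-5
rs2338258	FAM19A5	22q13.31	22	T	C	0.13	0.07	1.06	3.6e-5
rs5768143	FAM19A5	22q13.31	22	C	T	0.13	0.07	1.05	9.1e-5
rs17072597	MGC45800	4q34.3	4	C	T	0.22	0.14	1.05	1.5e-5
rs16864293	KCNE4	2q36.1	2	T	A	0.09	0.04	1.08	1.6e-5
rs1053226	SLC9A3	5p15.33	5	C	T	0.05	0.02	1.11	1.8e-5
rs41326844	SP3	2q31.1	2	T	C	0.47	0.36	1.03	2.5e-5
rs6555242	AHRR	5p15.33	5	T	G	0.07	0.03	1.09	3.1e-5
rs16956185	VAPA	18p11.22	18	G	A	0.15	0.08	1.06	3.2e-5
rs1503908	ZWINT	10q21.1	10	A	G	0.19	0.12	1.05	3.9e-5
rs319025	NOX4	11q14.3	11	T	C	0.67	0.56	1.03	4.1e-5
rs6893667	SPOCK1	5q31.2	5	C	T	0.06	0.02	1.10	4.2e-5
rs877455	C14orf64	14q32.2	14	G	A	0.10	0.05	1.07	4.8e-5
rs1001715	LDLRAD3	11p13	11	G	A	0.44	0.33	1.03	4.9e-5
rs12276510	LDLRAD3	11p13	11	G	A	0.43	0.33	1.03	5.5e-5
rs2450153	ST18	8q11.23	8	G	A	0.63	0.52	1.03	5.3e-5
rs3843918	ST18	8q11.23	8	T	C	0.46	0.44	1.03	7.0e-5
rs1872125	CYP2B6	19q13.2	19	T	C	0.24	0.16	1.04	5.7e-5
rs9506827	FGF9	13q12.11	13	T	C	0.29	0.20	1.04	5.9e-5
rs8016145	MIRN656	14q32.31	14	G	A	0.09	0.04	1.08	6.4e-5
rs349083	DLG2	11q14.1	11	G	A	0.47	0.36	1.03	6.5e-5
rs10968749	LOC646700	9p21.1	9	A	G	0.19	0.12	1.04	7.4e-5
rs9586032	SLC10A2	13q33.1	13	G	A	0.23	0.15	1.04	7.4e-5
rs2825256	PPIAL3	21q21.1	21	T	A	0.67	0.55	1.03	7.4e-5
rs2913472	HMP19	5q35.2	5	A	C	0.05	0.02	1.11	7.9e-5
rs4575680	ALK	2p23.2	2	G	C	0.08	0.04	1.07	9.0e-5
rs10501726	MIR1261	11q14.3	11	A	T	0.08	0.04	1.08	9.5e-5
rs767164	NRP1	10p11.22	10	T	A	0.30	0.21	1.04	9.8e-5
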
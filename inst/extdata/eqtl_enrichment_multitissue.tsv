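gene	fisher_p	empirical_p	log2fc	n_snps	up_plus	up_minus	down_plus	down_minus
VSIR	2.51e-05	0.006	0.63	51	25	1	5	10
HLCS	3.88e-05	0.014	-0.51	58	11	23	21	3
BICD2	0.0016	0.017	0.24	33	3	14	12	4
SLC5A1	0.0055	0.052	-1.62	25	3	5	16	1
PDGFD	0.0067	0.056	0.83	35	5	12	14	4
CAPN2	0.10	0.11	-0.35	13	2	4	6	1
LYN	0.027	0.14	0.40	29	4	12	9	4
PDE3A	0.14	0.16	-1.57	14	1	5	5	3
OGFOD1	0.034	0.17	-0.13	60	13	16	23	8
PLCB1	0.055	0.21	-0.67	40	15	6	7	12
FERMT2	0.11	0.25	-0.70	26	4	8	10	4
ADCY1	0.16	0.34	-0.37	52	18	11	9	14
HLA-DRA	0.32	0.37	0.69	18	8	2	4	4
TIAM1	0.23	0.41	0.44	46	18	9	9	10
STXBP1	0.39	0.41	-0.28	22	3	8	6	5
LRP5	0.31	0.42	-0.50	35	4	11	9	11
NDUFS5	0.39	0.44	-0.43	24	11	3	6	4
IL2RA	0.40	0.49	2.25	51	16	10	12	13
ANK2	0.46	0.59	-0.37	30	6	10	8	6
COL16A1	0.67	0.66	0.30	23	7	7	3	6
LAMB3	0.54	0.68	0.63	43	12	6	14	11
CPEB3	0.72	0.71	-0.49	39	16	12	5	6
GNG12	1	0.73	-0.34	16	1	3	4	8
CACNA1D	1	0.76	0.37	23	3	5	6	9
CPLX2	0.70	0.79	0.17	26	8	8	4	6
DOCK1	1	0.79	-0.29	34	7	7	11	9
PPARD	0.75	0.81	0.29	39	11	8	10	10
LEPR	1	0.88	-0.76	74	18	19	17	20
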
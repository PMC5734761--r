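gene	fisher_p	empirical_p	log2fc	n_snps	up_plus	up_minus	down_plus	down_minus
HLCS	0.00068	0.014	-0.51	22	1	17	4	0
HLA-DRA	0.0014	0.020	0.69	23	4	8	11	0
BICD2	0.0082	0.046	0.24	16	0	10	4	2
PDGFD	0.0065	0.066	0.83	18	0	2	16	0
NDUFS5	0.0098	0.080	-0.43	20	8	1	3	8
TIAM1	0.048	0.11	0.44	10	5	0	1	4
VSIR	0.027	0.16	0.63	24	7	1	5	11
LYZ	0.068	0.27	-1.46	32	4	14	8	6
LEPR	0.36	0.52	-0.76	44	13	13	6	12
OGFOD1	1	0.76	-0.13	13	2	2	4	5
SIPA1	1	0.83	0.42	26	1	3	9	13
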
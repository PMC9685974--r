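gene	hgvs	chrom	pos	ref	alt	consequence	cadd	acmg	region_flags	n_patients	af_case_sg	af_case_dbgap	af_gnomad	af_sg10k
KMT2C	NM_170606.3:c.C2689T	7	2689	C	T	stopgain	39.0	pathogenic	repetitive	7	1.21	0.11	0.02	NA
KMT2C	NM_170606.3:c.C2710T	7	2710	C	T	stopgain	37.0	pathogenic	repetitive	28	4.83	2.37	0.20	NA
RNF43	NM_001305545.1:c.C311T	17	311	C	T	nonsynonymous_snv	24.0	benign		7	1.21	17.81	0.06	1.64
RNF43	NM_001305545.1:c.G1589C	17	1589	G	C	nonsynonymous_snv	26.5	uncertain		3	0.52	NA	0.00	1.01
RNF43	NM_001305545.1:c.G647A	17	647	G	A	nonsynonymous_snv	25.4	benign		11	1.90	8.76	0.03	1.33
GPRIN2	NM_014696.4:c.C983G	10	983	C	G	nonsynonymous_snv	23.1	benign		17	2.93	20.92	0.10	NA
MUC4	NM_018406.7:c.G8461A	3	8461	G	A	nonsynonymous_snv	22.1	uncertain	repetitive	16	3.60	NA	0.00	0.04
H3F3A	NM_002107.6:c.C344G	1	344	C	G	nonsynonymous_snv	28.8	uncertain		14	2.41	0.65	0.71	NA
AKAP9	NM_005751.4:c.T3430C	7	3430	T	C	nonsynonymous_snv	20.5	uncertain		11	1.90	NA	0.43	1.62
TPTE2	NM_199254.2:c.483delT	13	483	CT	C	frameshift_deletion	22.0	uncertain	homopolymer;segmental_duplication	10	1.77	NA	0.08	0.04
HLA-B	NM_005514.8:c.A161G	6	161	A	G	nonsynonymous_snv	23.6	uncertain		9	1.55	5.71	0.30	1.05
NRG1	NM_013962.2:c.G172A	8	172	G	A	nonsynonymous_snv	23.6	benign		9	1.55	33.33	0.06	3.40
ELN	NM_001278913.2:c.G1498C	7	1498	G	C	nonsynonymous_snv	23.2	benign		8	1.38	8.91	0.03	1.25
ERBB3	NM_001982.3:c.A3355T	12	3355	A	T	nonsynonymous_snv	23.8	benign		8	1.38	11.51	0.11	1.60
HLA-A	NM_001242758.1:c.268delA	6	268	CA	C	frameshift_deletion	2.03	uncertain	polymorphic_locus	8	1.38	0.21	0.04	0.94
HLA-A	NM_001242758.1:c.C791T	6	791	C	T	nonsynonymous_snv	25.6	uncertain	polymorphic_locus	8	1.38	NA	0.13	1.95
HLA-A	NM_001242758.1:c.G1055T	6	1055	G	T	nonsynonymous_snv	23.6	uncertain	polymorphic_locus	8	1.38	0.11	0.14	3.46
HLA-A	NM_001242758.1:c.G565A	6	565	G	A	nonsynonymous_snv	22.1	uncertain	polymorphic_locus	8	1.38	0.11	0.15	7.04
HLA-A	NM_001242758.1:c.G684A	6	684	G	A	stopgain	37.0	uncertain	polymorphic_locus	8	1.38	NA	0.06	1.31
HLA-A	NM_001242758.1:c.T547C	6	547	T	C	nonsynonymous_snv	24.4	uncertain	polymorphic_locus	3	0.52	0.11	0.02	0.21
ROS1	NM_002944.2:c.C3326T	6	3326	C	T	nonsynonymous_snv	21.1	benign		8	1.55	7.83	0.27	1.64
HLA-DRB1	NM_002124.3:c.118_122del	6	118	CNNNNN	C	frameshift_deletion	24.7	uncertain	polymorphic_locus	7	4.09	0.15	0.07	0.24
HLA-DRB1	NM_002124.3:c.126_127insTTAAGTTT	6	126	C	CTTAAGTTT	frameshift_insertion	24.6	uncertain	polymorphic_locus	7	2.83	NA	0.05	0.13
HLA-DRB1	NM_002124.3:c.C301T	6	301	C	T	nonsynonymous_snv	25.5	likely_benign	polymorphic_locus	4	0.99	0.00	0.00	0.06
NTRK1	NM_001012331.1:c.C1792T	1	1792	C	T	nonsynonymous_snv	27.8	benign		6	1.03	6.01	0.03	1.16
NTRK1	NM_001012331.1:c.G1820T	1	1820	G	T	nonsynonymous_snv	22.0	benign		5	0.86	6.02	0.03	1.13
CHIC2	NM_012110.4:c.G36T	4	36	G	T	nonsynonymous_snv	22.2	uncertain		5	0.86	NA	0.03	0.37
CNTRL	NM_001330762.2:c.G1009A	9	1009	G	A	nonsynonymous_snv	21.9	uncertain		5	0.86	5.52	0.02	0.82
ISX	NM_001303508.2:c.G248A	22	248	G	A	nonsynonymous_snv	34.0	uncertain		5	0.86	5.15	0.04	1.41
MYO5A	NM_000259.3:c.A3960T	15	3960	A	T	nonsynonymous_snv	21.7	benign		5	0.86	NA	0.01	0.19
TET2	NM_001127208.2:c.C1088T	4	1088	C	T	nonsynonymous_snv	23.3	uncertain		5	1.03	4.94	0.04	0.82
BRD7	NM_001173984.3:c.A44C	16	44	A	C	nonsynonymous_snv	22.8	uncertain	segmental_duplication	4	0.80	NA	NA	NA
CBFA2T3	NM_005187.6:c.G308C	16	308	G	C	nonsynonymous_snv	22.5	benign		4	0.69	9.55	0.01	0.53
DCC	NM_005215.4:c.A3578G	18	3578	A	G	nonsynonymous_snv	23.1	uncertain		4	0.69	NA	0.10	0.65
PTPRB	NM_001206971.3:c.C3412T	12	3412	C	T	nonsynonymous_snv	25.1	uncertain		4	0.69	2.15	0.01	0.44
RNF213	NM_001256071.3:c.C12847A	17	12847	C	A	nonsynonymous_snv	23.1	benign		3	0.52	6.55	0.00	0.39
RNF213	NM_001256071.3:c.C13945G	17	13945	C	G	nonsynonymous_snv	24.4	benign		4	0.69	8.37	0.00	0.53
CLIP1	NM_001247997.1:c.C80T	12	80	C	T	nonsynonymous_snv	23.3	likely_benign		3	0.52	1.29	0.00	0.04
CUX1	NM_001202543.2:c.C3317T	7	3317	C	T	nonsynonymous_snv	24.8	uncertain		3	0.52	NA	0.01	0.09
FBLN2	NM_001998.3:c.G2569T	3	2569	G	T	nonsynonymous_snv	29.0	uncertain		3	0.52	0.22	0.00	1.34
GNAS	NM_016592.4:c.A266G	20	266	A	G	nonsynonymous_snv	23.8	uncertain		3	0.52	NA	0.00	0.03
MAF	NM_001031804.3:c.G655T	16	655	G	T	nonsynonymous_snv	22.2	uncertain	repetitive	3	4.81	NA	0.00	NA
MGA	NM_001080541.2:c.C1883A	15	1883	C	A	nonsynonymous_snv	25.8	uncertain		3	0.52	1.54	0.00	0.08
MLLT1	NM_005934.4:c.G889A	19	889	G	A	nonsynonymous_snv	24.8	uncertain		3	0.52	3.00	0.03	0.20
NBEA	NM_015678.4:c.C2317A	13	2317	C	A	nonsynonymous_snv	27.3	uncertain	segmental_duplication	3	0.99	NA	NA	NA
NUP214	NM_001318324.2:c.A2263G	9	2263	A	G	nonsynonymous_snv	23.6	uncertain		3	0.52	1.29	0.02	1.01
PDGFRB	NM_001355016.2:c.G1261A	5	1261	G	A	nonsynonymous_snv	21.2	benign		3	0.52	3.54	0.00	0.18
RABEP1	NM_001291581.2:c.G1755C	17	1755	G	C	nonsynonymous_snv	22.6	uncertain		3	0.52	4.51	0.00	0.36
ZNF479	NM_001370129.1:c.T1421C	7	1421	T	C	nonsynonymous_snv	23.3	likely_benign		3	0.52	2.58	0.00	0.54
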
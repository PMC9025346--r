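no	name	max_array_len	gc_percent	abundance_percent	assembly	chromosomes	te_similarity	similarity_class
1	272A	5953	44	1.0711	AMDS	X	B1	SINE
2	11A	13947	50	0.9855	AFTD	9-10	ERV2	LTR
3	49A	2075	32	0.8666	APMK	8	ERV	LTR
4	767A	7543	42	0.66232	AMDS	NA	ERV2	LTR
5	6A	36714	59	0.5978	AFTD	5, 6, 8-10
6	33A	29248	46	0.5119	AFTD	5	SAU1.5	Satellite
7	79A	12802	34	0.4047	AFTD	5, 9-10, 6, X
8	25B	14645	49	0.1788	AMDS	9-10
9	304A	4935	36	0.1365	AFTD	NA	ERV2	LTR
10	72A	40914	39	0.1284	AFTD	1
11	77A	3456	40	0.0761	APMK	5, 2, 8
12	84A	2885	39	0.0715	APMK	all	Zn-finger	Gene
13	26A	28887	45	0.0569	AFTD	X
14	17A	15866	41	0.0340	APMK	6
15	65A	3391	39	0.0296	APMK	X	Tc1	DNA
16	25A	13526	43	0.0232	APMK	5
17	27A	2668	46	0.0172	APMK	6
18	62A	8036	36	0.0076	APMK	2
19	18A	11035	49	0.0074	AFTD	6, 2, 9-10
20	24B	5004	48	0.0004	APMK	7
21	13A	1769	48	0.0003	APMK	3
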
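index	abbreviation	x	y	z
1	PreCG_L	-39	-6	51
2	PreCG_R	39	-6	51
3	SFGdor_L	-20	31	44
4	SFGdor_R	20	31	44
5	ORBsup_L	-17	47	-13
6	ORBsup_R	17	47	-13
7	MFG_L	-35	33	33
8	MFG_R	35	33	33
9	ORBmid_L	-31	50	-10
10	ORBmid_R	31	50	-10
11	IFGoperc_L	-49	13	19
12	IFGoperc_R	49	13	19
13	IFGtriang_L	-47	30	14
14	IFGtriang_R	47	30	14
15	ORBinf_L	-39	31	-12
16	ORBinf_R	39	31	-12
17	ROL_L	-49	-8	14
18	ROL_R	49	-8	14
19	SMA_L	-6	5	61
20	SMA_R	6	5	61
21	OLF_L	-9	15	-12
22	OLF_R	9	15	-12
23	SFGmed_L	-6	49	31
24	SFGmed_R	6	49	31
25	ORBmed_L	-6	54	-7
26	ORBmed_R	6	54	-7
27	REC_L	-6	37	-18
28	REC_R	6	37	-18
29	INS_L	-37	7	3
30	INS_R	37	7	3
31	ACG_L	-5	35	14
32	ACG_R	5	35	14
33	MCG_L	-6	-15	42
34	MCG_R	6	-15	42
35	PCG_L	-5	-43	25
36	PCG_R	5	-43	25
37	HIP_L	-27	-21	-10
38	HIP_R	27	-21	-10
39	PHG_L	-22	-16	-21
40	PHG_R	22	-16	-21
41	AMYG_L	-24	-1	-17
42	AMYG_R	24	-1	-17
43	CAL_L	-9	-79	6
44	CAL_R	9	-79	6
45	CUN_L	-8	-80	27
46	CUN_R	8	-80	27
47	LING_L	-16	-68	-5
48	LING_R	16	-68	-5
49	SOG_L	-18	-84	28
50	SOG_R	18	-84	28
51	MOG_L	-34	-81	16
52	MOG_R	34	-81	16
53	IOG_L	-39	-76	-8
54	IOG_R	39	-76	-8
55	FFG_L	-33	-40	-20
56	FFG_R	33	-40	-20
57	PoCG_L	-44	-23	49
58	PoCG_R	44	-23	49
59	SPG_L	-25	-60	59
60	SPG_R	25	-60	59
61	IPL_L	-45	-46	50
62	IPL_R	45	-46	50
63	SMG_L	-56	-32	34
64	SMG_R	56	-32	34
65	ANG_L	-45	-61	36
66	ANG_R	45	-61	36
67	PCUN_L	-9	-56	44
68	PCUN_R	9	-56	44
69	PCL_L	-6	-25	70
70	PCL_R	6	-25	70
71	CAU_L	-13	11	9
72	CAU_R	13	11	9
73	PUT_L	-25	4	2
74	PUT_R	25	4	2
75	PAL_L	-20	0	0
76	PAL_R	20	0	0
77	THA_L	-12	-18	8
78	THA_R	12	-18	8
79	HES_L	-43	-19	10
80	HES_R	43	-19	10
81	STG_L	-55	-21	7
82	STG_R	55	-21	7
83	TPOsup_L	-41	15	-20
84	TPOsup_R	41	15	-20
85	MTG_L	-56	-34	-2
86	MTG_R	56	-34	-2
87	TPOmid_L	-40	15	-32
88	TPOmid_R	40	15	-32
89	ITG_L	-52	-32	-22
90	ITG_R	52	-32	-22
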
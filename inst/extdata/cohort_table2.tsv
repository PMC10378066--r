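sample_id	age	menopause	histotype	figo	grade_class	myometrial_invasion	lvi
5	39	premenopausal	dedifferentiated	IB	HG	gt50	yes
7	50	premenopausal	endometrioid G1	IB	LG	none	no
8	83	postmenopausal	dedifferentiated	IB	HG	gt50	no
9	41	premenopausal	endometrioid G1	IA	LG	lt50	no
10	53	postmenopausal	endometrioid G1	IA	LG	none	no
13	64	postmenopausal	endometrioid G1	IV	LG	lt50	unknown
14	73	postmenopausal	endometrioid G1	IB	LG	gt50	no
16	69	postmenopausal	endometrioid G1	IA	LG	lt50	no
18	79	postmenopausal	endometrioid G1	IB	LG	gt50	no
19	74	postmenopausal	endometrioid G1	IA	LG	lt50	no
20	76	postmenopausal	endometrioid G1	IA	LG	lt50	no
21	53	premenopausal	endometrioid G2	IA	LG	none	no
23	45	premenopausal	endometrioid G1	IA	LG	none	no
24	69	postmenopausal	endometrioid G2	IB	LG	gt50	yes
25	54	premenopausal	endometrioid G3	IA	HG	lt50	no
26	72	postmenopausal	endometrioid G1	IA	LG	lt50	no
30	54	premenopausal	endometrioid G1	IA	LG	none	no
33	77	postmenopausal	endometrioid G3	IB	HG	gt50	no
34	57	postmenopausal	mucinous	IA	LG	lt50	no
40	71	postmenopausal	serous	IA	HG	lt50	no
44	73	postmenopausal	serous	IB	HG	gt50	yes
47	27	premenopausal	dedifferentiated	IA	HG	lt50	no
49	70	postmenopausal	endometrioid G1	IA	LG	lt50	no
50	73	postmenopausal	endometrioid G1	IA	LG	lt50	no
51	75	postmenopausal	endometrioid G2	IA	LG	gt50	yes
52	75	postmenopausal	endometrioid G2	IA	LG	lt50	yes
53	50	postmenopausal	endometrioid G3	IA	HG	lt50	yes
54	71	postmenopausal	endometrioid G1	IA	LG	lt50	no
56	55	postmenopausal	endometrioid G1	IA	LG	none	no
57	43	premenopausal	endometrioid G1	IA	LG	none	no
62	59	postmenopausal	endometrioid G1	IA	LG	none	no
63	66	postmenopausal	endometrioid G1	IA	LG	lt50	no
65	80	postmenopausal	carcinosarcoma	IB	HG	gt50	yes
66	72	postmenopausal	endometrioid G1	IA	LG	lt50	no
68	45	premenopausal	endometrioid G1	II	LG	lt50	no
71	48	premenopausal	serous	IA	HG	lt50	no
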
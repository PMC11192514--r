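id	age	sex	months_post_stroke	lesion_volume_mm3	ifo_spared_pct	stg_spared_pct	heschl_spared_pct	subtype	wab_aq	palpa7_pct	palpa8_pct	pal7_pct	err_omissions	err_misselections	err_distortions	err_other_words	err_total
s01	58	F	49	56664	96	39	27	anomic	97	100.0	76.7	87.5	0	2	0	1	6
s02	58	M	48	73912	100	51	7	anomic	82	95.8	66.7	70.0	0	0	3	1	6
s03	52	M	141	265360	17	6	1	Broca's + apraxia	64	73.3	43.3	72.5	19	22	0	1	61
s04	51	M	85	285800	28	16	5	Broca's	36	87.5	53.3	55.0	37	4	1	72	125
s05	51	M	89	50464	95	94	81	anomic	95	95.8	96.7	95.0	0	2	0	0	2
s06	57	M	163	193304	62	33	7	Broca's	50	91.7	53.3	65.0	104	25	1	58	189
s07	54	F	32	80520	100	63	77	anomic	85	87.5	43.3	40.0	16	21	0	3	40
s08	56	M	29	70424	100	39	1	anomic	95	100.0	66.7	57.5	0	2	0	0	2
s09	55	F	117	217520	24	4	0	anomic	92	100.0	86.7	80.0	0	3	0	1	4
s10	52	M	85	76792	75	29	12	anomic + apraxia	86	100.0	86.7	92.5	35	24	9	55	124
s11	63	M	177	136464	42	45	21	Broca's	73	100.0	73.3	75.0	24	48	1	70	149
s12	58	F	62	107872	14	89	71	anomic	85	83.3	63.3	72.5	27	61	10	50	149
s13	46	M	49	43648	44	91	86	anomic + apraxia	94	62.5	53.3	50.0	1	3	3	2	9
s14	53	M	470	119968	20	29	22	anomic	91	n/a	80.0	n/a	23	15	2	15	58
s15	62	M	19	95424	59	48	32	Broca's	56	100.0	3.3	52.5	1	92	10	21	137
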
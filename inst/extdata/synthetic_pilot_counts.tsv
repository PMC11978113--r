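taxon_id	ctrl_001	ctrl_002	ctrl_003	ctrl_004	ctrl_005	ctrl_006	ctrl_007	ctrl_008	ctrl_009	ctrl_010	trt_001	trt_002	trt_003	trt_004	trt_005	trt_006	trt_007	trt_008	trt_009	trt_010
taxon00001	59	112	76	69	124	74	122	93	109	81	68	46	83	49	88	94	79	95	66	55
taxon00002	223	301	235	346	207	304	293	322	238	171	316	401	266	646	317	433	362	260	302	326
taxon00003	710	371	471	456	584	746	595	712	673	475	358	359	280	156	356	384	573	369	344	417
taxon00004	32	37	50	30	30	35	40	20	57	38	67	43	41	59	39	94	71	28	57	34
taxon00005	32	13	24	29	12	25	27	29	16	14	17	18	9	24	27	12	24	15	26	7
taxon00006	3	15	23	9	23	4	4	10	18	11	1	5	6	5	5	0	2	3	1	1
taxon00007	2524	2456	2043	1425	2360	1815	2812	1628	1744	2032	1284	1087	1741	1887	1486	2181	2209	2168	1802	1710
taxon00008	8	8	7	7	8	11	10	5	11	20	4	3	12	5	11	12	5	12	2	19
taxon00009	11	25	19	41	23	17	21	24	25	16	29	26	29	27	31	13	43	41	39	25
taxon00010	24	15	13	12	5	14	13	12	7	4	47	56	44	81	69	69	66	39	72	34
taxon00011	503	854	1062	801	863	969	1277	955	596	585	657	1141	1218	882	1061	1163	525	1215	898	995
taxon00012	54	116	58	58	35	57	65	70	80	63	45	69	84	41	61	69	64	75	75	86
taxon00013	22	25	25	37	36	13	34	25	29	31	8	9	13	14	15	15	16	13	14	10
taxon00014	222	182	219	248	227	246	293	172	280	262	186	210	129	199	211	137	129	171	101	215
taxon00015	453	455	448	368	427	459	373	315	284	301	192	199	308	164	145	155	216	182	199	253
taxon00016	20	7	2	6	9	11	9	5	16	1	2	4	7	3	6	5	1	4	4	5
taxon00017	86	105	83	84	101	50	127	53	121	101	112	112	98	63	75	71	77	57	78	113
taxon00018	58	62	29	54	60	43	53	55	65	100	64	38	62	60	38	47	77	48	40	47
taxon00019	6	5	9	13	1	6	6	16	7	5	1	3	2	0	6	1	2	1	2	1
taxon00020	63	68	41	51	68	43	77	74	63	89	94	75	97	105	158	97	95	102	72	92
taxon00021	33	13	41	34	35	37	59	38	58	23	12	13	7	8	13	22	21	9	7	9
taxon00022	8	21	7	3	11	17	22	6	6	10	12	17	38	30	19	19	33	26	31	19
taxon00023	172	161	212	148	108	93	177	132	102	81	92	182	131	102	105	108	87	126	113	103
taxon00024	631	735	569	590	673	957	551	594	1112	789	442	850	627	450	555	660	710	553	442	852
taxon00025	0	0	0	0	1	3	2	7	2	0	0	0	0	0	0	0	2	1	0	2
taxon00026	51	77	74	46	38	76	46	81	62	76	38	27	24	15	42	51	19	45	30	32
taxon00027	9	3	8	9	3	9	4	4	6	7	17	6	15	11	14	1	8	9	12	16
taxon00028	69	43	73	61	78	48	37	60	89	43	107	96	132	132	80	88	99	113	107	95
taxon00029	6	6	5	4	4	8	11	0	2	9	1	3	6	3	6	12	4	1	3	4
taxon00030	32	72	30	33	32	25	58	49	54	36	105	76	161	127	77	77	80	50	136	100
taxon00031	36	74	104	43	18	44	77	49	58	32	10	15	17	34	40	18	23	28	11	18
taxon00032	28	40	37	23	17	36	23	22	37	40	45	40	58	32	9	61	63	40	31	30
taxon00033	578	1126	1462	417	553	624	1113	657	960	604	376	340	237	290	248	305	451	542	401	361
taxon00034	232	433	449	497	326	354	349	544	450	298	499	715	731	1328	916	780	803	674	401	387
taxon00035	2	1	2	1	17	8	8	12	10	3	0	5	4	1	5	3	4	0	5	6
taxon00036	0	11	3	12	14	17	3	13	9	4	12	8	3	3	11	17	6	5	6	7
taxon00037	11	17	2	26	11	26	14	18	17	17	16	18	21	33	22	18	8	33	31	26
taxon00038	304	245	105	124	276	199	178	160	183	156	139	121	136	123	109	96	101	179	135	167
taxon00039	8	1	4	5	2	8	0	6	5	4	5	13	11	1	0	5	2	4	0	1
taxon00040	30	53	20	29	20	26	41	33	49	24	91	70	12	106	34	77	85	121	36	69
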
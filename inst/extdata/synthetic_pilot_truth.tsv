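taxon_id	x	M	lfc	dispersion	mu_control	mu_treatment
taxon00001	6.41434914036441	85.2926276070054	-0.178273298829221	0.077586514123019	90.5557216702037	80.0295335438072
taxon00002	8.23119950878529	300.495485972688	0.385551700434384	0.0649917555172071	260.579946687445	340.411025257931
taxon00003	8.74565332998485	429.243753623533	-0.487942678175699	0.0634945179454273	501.148199330811	357.339307916256
taxon00004	5.44119143686206	43.4472041535589	0.601343277139122	0.094524661119699	34.5212446003937	52.3731637067242
taxon00005	4.06446518528173	16.7311555586439	-0.252804129661935	0.149653102246428	18.1933201944216	15.2689909228662
taxon00006	3.14528456727044	8.84759021509726	-1.63221549731211	0.229537689193657	13.3791635196249	4.31601691056958
taxon00007	10.9434021813673	1969.21126358894	-0.31917723636884	0.060761726295058	2186.15810034018	1752.2644268377
taxon00008	3.03324524442525	8.18649126519593	-0.371343802995617	0.243228681422663	9.23429733325905	7.13868519713282
taxon00009	4.93625032151399	30.6167729036997	0.459518100631164	0.108992753244047	25.7816508278336	35.4518949795659
taxon00010	4.9755249078077	31.4617040462982	1.9631617556189	0.107677010685519	12.8437249758312	50.0796831167652
taxon00011	9.84791762554218	921.549356328443	0.37036343106192	0.0616276936115241	803.906334479621	1039.19237817727
taxon00012	5.99729690803905	63.8801992702231	0.0640962788822881	0.0834814546156121	62.4613929427098	65.2990055977363
taxon00013	4.50815297822571	22.7556513694107	-1.34056084813273	0.12591769119896	32.6276976790961	12.8836050597253
taxon00014	7.61862415316296	196.532507758239	-0.271286388816295	0.0676323251410662	214.95637490848	178.108640607998
taxon00015	8.23302143506822	300.875210342957	-0.885003690849818	0.0649854555923374	390.370309570992	211.380111114923
taxon00016	2.60421764367983	6.08061667279395	-0.972964075869181	0.306685505881556	8.05668727271655	4.10454607287136
taxon00017	6.44788520594626	87.2985148851356	0.0412725594937432	0.0771824228851275	86.0498839077412	88.5471458625299
taxon00018	5.68225860897815	51.3487983034461	-0.164599787987562	0.0892119786549967	54.2748653915881	48.4227312153041
taxon00019	2.45411177443458	5.47975645376275	-2.09804079366479	0.333734793262574	8.88434902288379	2.0751638846417
taxon00020	6.31890198085365	79.8323724715424	0.418386397156386	0.0787893701960906	68.3369972619457	91.3277476811391
taxon00021	4.4923284086478	22.5074141026101	-1.37489746443482	0.12664470619155	32.4880733341945	12.5267548710257
taxon00022	4.22784964321341	18.7374099964343	1.07984750837357	0.140053753442202	12.0350272517426	25.4397927411261
taxon00023	6.91664183493475	120.813832552242	0.163683442007199	0.0724157968364373	113.967604576596	127.660060527889
taxon00024	9.31472590915961	636.812969896574	-0.297779655252266	0.0623554796634302	702.301365649321	571.324574143827
taxon00025	-0.20122787112804	0.869809956915153	-1.01769907306672	1.78451463457588	1.16447948731791	0.575140426512396
taxon00026	5.61505904117133	49.0118616382576	-0.771935475757583	0.0906048362551716	61.8199983646708	36.2037249118443
taxon00027	3.25570717935957	9.55136667995002	0.41048948191521	0.217045588371009	8.20163686952515	10.9010964903749
taxon00028	6.44125534271112	86.8982574809043	0.476115782794136	0.077261565921844	72.6879883355819	101.108526626227
taxon00029	2.29215404172683	4.89786850467941	-0.293014582259823	0.366255669903531	5.39354976092678	4.40218724843204
taxon00030	6.0969856755111	68.4503339793467	1.24218283409414	0.0819136987768766	40.6769143635975	96.2237535950959
taxon00031	5.29676715493843	39.3084386415166	-1.69016278538399	0.0981597451295289	60.0178334460449	18.5990438369884
taxon00032	5.20826483763144	36.9695310335407	0.590079233917128	0.100573952605434	29.5127105867805	44.4263514803009
taxon00033	9.00159786282843	512.56738185165	-1.08793427472347	0.062926444508781	697.164528014281	327.970235689019
taxon00034	9.16597068066369	574.423388127452	0.758153367418528	0.0626113142866446	426.870425525555	721.976350729348
taxon00035	2.24450638167799	4.73874944253584	0.0680431856025363	0.376539208960014	4.62702110028869	4.85047778478299
taxon00036	2.87246888720902	7.32317304699631	0.174591211962803	0.264829244150559	6.88059734570741	7.76574874828522
taxon00037	4.07717039079987	16.8791504826715	0.622723771438541	0.148867031640007	13.2918235314059	20.4664774339371
taxon00038	7.2652364064081	153.834620297376	-0.304531243750636	0.069750730993455	170.010690274561	137.658550320191
taxon00039	1.77581200638532	3.42430689711794	0.439692626880785	0.498044849678185	2.90649291090423	3.94212088333164
taxon00040	5.76040527135202	54.2069252660801	0.471093354075986	0.0876717410669781	45.4344510350585	62.9793994971017
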
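taxon	sample1	sample2	sample3	sample4	sample5	sample6	sample7	sample8	sample9	sample10	sample11	sample12	sample13	sample14	sample15	sample16	sample17	sample18	sample19	sample20	sample21	sample22	sample23	sample24	sample25	sample26	sample27	sample28	sample29	sample30
taxon1	480	121	857	107	461	501	210	17	72	132	35	707	22	74	0	78	28	156	263	83	13	444	1070	19	44	916	92	106	258	0
taxon2	9	8	269	100	83	304	44	3	87	78	64	20	6	61	0	32	7	137	28	421	7	4	136	59	29	0	9	3	33	0
taxon3	1	9	25	11	0	5	24	52	6	7	12	60	9	0	5207	120	3	21	37	42	7	30	7	2	5	542	7	4	6	0
taxon4	32	3	96	20	20	5	1474	1	10	82	43	4	2	167	0	3	0	2	3	55	1	1	15	24	5	67	50	5	44	0
taxon5	190	55	622	117	171	1969	1044	8	209	146	226	2645	2568	100	0	117	23	1369	171	53	75	785	342	365	162	328	234	57	195	0
taxon6	577	1930	1100	478	33	242	180	51	523	159	487	8	25	288	0	401	115	3196	350	643	21	32	21	587	79	238	133	993	933	4158
taxon7	37	28	78	21	72	260	21	11	45	130	126	153	0	76	0	12	5	5	368	15	3	10	55	70	2216	210	26	11	16	0
taxon8	5	22	8	1	13	5	1	4	9	12	32	56	4	7	0	21	0	15	42	20	18	8	1	5	5	21	20	2	8	0
taxon9	2	0	33	0	0	0	0	0	1	3	2	2	0	1	0	1	0	8	10	2	1	0	0	2	3	0	3	2	3	0
taxon10	1	5	6	0	33	2	0	0	16	35	20	11	806	27	0	2	0	81	14	4	1	0	1	1	1	28	1	0	6	0
taxon11	2	1	5	7	0	1	0	1	4	4	7	1	0	0	0	2	0	5	0	0	0	0	3	0	0	2	3	1	3	0
taxon12	63	54	166	32	14	81	15	9	32	100	21	87	2	78	0	294	4	378	23	150	2384	16	11	59	11	187	230	9	200	0
taxon13	47	41	650	5	77	350	21	6	59	16	125	142	3	990	0	2598	14	655	28	584	15	242	118	175	54	84	112	31	126	0
taxon14	19	76	345	32	281	204	24	0	475	87	179	2406	12	57	0	11	6	79	18	10	336	5	26	0	38	143	12	29	312	0
taxon15	0	0	0	49	1	0	0	0	0	0	2	0	0	0	0	0	0	0	0	0	2	0	0	0	0	0	0	0	0	0
taxon16	10	8	236	12	3	17	0	53	5	10	170	20	2	3	0	89	1	11	25	38	3	5	11	7	3	15	46	107	59	0
taxon17	2	0	6	2	5	3	2	0	23	1	1	3	0	0	0	0	2	15	1	5	0	0	4	2	3	1	0	1	0	0
taxon18	1147	4	27	5	21	170	33	2	109	30	245	31	4	0	0	14	55	22	120	30	6	2	2607	58	14	6	1752	17	48	0
taxon19	0	1	1	2	1	0	2	0	0	0	1	2	0	2	0	4	0	2	0	2	0	0	0	0	0	3	0	0	1	0
taxon20	0	0	6	1	2	0	0	0	0	1	2	1	1	0	0	0	0	4	1	1	0	2	2	1	0	0	0	0	0	0
taxon21	54	57	1439	209	131	56	302	26	24	217	748	1070	3	264	0	97	5628	1025	807	321	5	363	51	182	128	183	1107	248	247	0
taxon22	7	109	358	14	63	32	28	7	19	112	287	68	2	6	0	7	14	147	17	84	6	1	339	90	2	138	449	31	10	0
taxon23	56	35	826	194	2063	66	75	1436	6	72	61	2	20	53	0	51	19	887	128	53	8	160	165	89	39	23	1085	8	82	0
taxon24	29	10	10	2	1	33	5	0	0	12	20	8	2	7	0	2	5	45	0	32	1	1	9	22	6	9	9	3	0	0
taxon25	7	95	242	973	0	289	153	2	110	40	326	406	28	63	0	6	49	180	86	36	9	17	20	86	22	2	12	78	812	0
taxon26	0	1	9	1	0	1	0	0	1	1	14	3	1	0	0	0	0	0	0	3	1	0	2	2	0	3	0	1	11	0
taxon27	8	4	34	1	2	29	16	2	98	7	16	8	0	43	0	14	5	259	32	63	11	11	15	30	19	8	28	12	6	0
taxon28	19	16	350	129	57	52	31	21	42	331	771	47	21	38	0	21	7	209	28	1420	15	21	113	18	46	47	5	15	51	0
taxon29	1	1	2	1	0	1	0	0	0	0	0	0	0	16	0	0	0	0	0	1	0	0	0	0	0	1	0	55	2	0
taxon30	3	3	27	5	8	139	6	1	5	5	45	24	1	3	0	17	8	31	1	18	3	19	24	8	2	33	15	1	30	0
taxon31	1	1	16	0	11	13	0	0	40	17	79	2	1	1	0	0	0	13	0	2	3	0	4	2	6	12	2	2	5	0
taxon32	5	40	34	1	7	31	21	0	7	2	2	17	5	27	0	34	0	4	22	16	16	0	11	11	4	4	7	8	0	0
taxon33	2	4	48	16	1	6	16	0	340	13	7	0	0	13	0	6	2	27	10	60	4	0	58	52	1	0	1	0	16	0
taxon34	83	104	67	64	309	381	306	2082	100	2462	252	504	56	20	0	344	2931	174	300	104	33	184	280	806	25	31	83	70	268	0
taxon35	3	13	23	0	13	5	0	1	7	3	25	36	0	8	0	2	1	1	10	6	0	0	0	1	6	0	3	8	10	0
taxon36	1745	111	944	11	63	61	1	2	38	22	39	75	0	675	0	167	27	68	14	3	9	7	71	9	33	52	13	5	1	0
taxon37	7	23	19	4	408	7	75	0	106	45	1050	111	30	62	0	67	21	422	12	162	12	3	9	1	8	19	10	46	18	0
taxon38	8	1	24	4	183	0	7	0	4	8	26	11	1	7	0	27	0	3	0	9	21	0	9	30	17	0	2	2	82	0
taxon39	0	1	38	1	11	5	0	0	24	3	2	7	1	2	0	2	41	9	15	329	0	1774	28	6	158	3	10	0	2	0
taxon40	584	12	57	10	3	1	256	8	1633	65	29	79	0	2	0	45	36	9	2267	31	20	69	32	0	7	331	63	1	36	0
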
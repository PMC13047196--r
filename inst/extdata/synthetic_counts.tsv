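sample_id	OTU_1	OTU_2	OTU_3	OTU_4	OTU_5	OTU_6	OTU_7	OTU_8	OTU_9	OTU_10	OTU_11	OTU_12	OTU_13	OTU_14	OTU_15	OTU_16	OTU_17	OTU_18	OTU_19	OTU_20	OTU_21	OTU_22	OTU_23	OTU_24	OTU_25	OTU_26	OTU_27	OTU_28	OTU_29	OTU_30	OTU_31	OTU_32	OTU_33	OTU_34	OTU_35	OTU_36	OTU_37	OTU_38	OTU_39	OTU_40	OTU_41	OTU_42	OTU_43	OTU_44	OTU_45	OTU_46	OTU_47	OTU_48	OTU_49	OTU_50	OTU_51	OTU_52	OTU_53	OTU_54	OTU_55	OTU_56	OTU_57	OTU_58	OTU_59	OTU_60
CT0_S1_R1	0	0	0	0	0	0	0	0	0	1	0	58	4	0	10	0	913	1	13	268	0	0	0	0	0	3	0	0	355	109	0	0	1258	0	0	0	0	0	0	0	0	0	0	6	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
CT0_S1_R2	0	0	0	0	0	0	0	0	0	3	2	68	2	0	1	4	8	0	3	1525	0	0	0	0	0	0	0	0	1176	102	0	0	29	0	0	0	0	0	0	0	0	0	0	77	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
CT0_S1_R3	0	0	0	0	0	0	0	0	0	12	1	438	220	0	40	9	99	2	47	388	0	0	0	0	0	0	0	0	172	85	0	0	37	0	0	0	0	0	0	0	0	0	0	1450	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
CT0_S2_R1	0	0	0	0	0	0	0	0	0	2	6	1	128	1	547	324	17	45	0	18	0	0	0	0	0	1672	0	11	15	19	1	1	142	0	0	0	0	8	0	0	0	0	0	1	0	10	28	3	0	0	0	0	0	0	0	0	0	0	0	0
CT0_S2_R2	0	0	0	0	0	0	0	0	0	16	1670	57	409	4	79	11	42	135	0	1	0	1	0	0	0	3	0	20	157	0	5	17	57	0	0	0	0	1	0	0	0	0	0	2	0	73	240	0	0	0	0	0	0	0	0	0	0	0	0	0
CT0_S2_R3	0	0	0	0	0	0	0	0	0	6	24	116	662	0	72	129	10	4	1	1	0	1	0	0	0	101	0	0	623	0	0	0	34	0	0	0	0	822	0	0	0	0	0	2	0	53	339	0	0	0	0	0	0	0	0	0	0	0	0	0
CT50_S1_R1	0	0	0	0	0	0	0	0	0	0	0	0	0	333	0	0	0	112	0	0	5	151	13	18	0	3	748	307	0	0	1	20	0	2	42	0	573	343	0	65	0	0	0	0	6	13	11	46	5	0	3	0	0	98	32	0	0	7	43	0
CT50_S1_R2	0	0	0	0	0	0	0	0	0	0	0	0	0	1484	0	0	0	6	0	0	5	99	0	18	0	0	3	2	0	0	3	6	0	0	63	0	1	997	0	2	0	0	0	0	2	2	2	0	21	0	1	0	0	0	0	0	0	1	282	0
CT50_S1_R3	0	0	0	0	0	0	0	0	0	0	0	0	0	22	0	0	0	7	0	0	25	37	6	0	0	1	4	1	0	0	46	859	0	0	1	0	47	1	0	22	0	0	0	0	0	0	7	21	122	0	27	0	0	12	0	0	0	2	1730	0
CT50_S2_R1	0	0	0	0	0	0	14	0	0	0	0	0	0	6	0	0	0	0	0	0	1233	2	59	1	0	0	3	49	0	0	0	0	0	10	131	2	13	2	0	95	1	30	0	0	451	0	2	4	44	34	703	0	9	5	59	0	0	9	27	2
CT50_S2_R2	0	0	0	0	0	0	4	0	0	0	0	0	0	157	0	0	0	0	0	0	1556	5	11	0	0	0	94	10	0	0	0	0	0	42	5	7	10	29	0	522	1	52	0	0	94	0	0	0	0	0	155	0	5	144	3	0	1	14	77	2
CT50_S2_R3	0	0	0	0	0	0	3	0	0	0	0	0	0	145	0	0	0	0	0	0	321	18	30	132	2	0	6	0	0	0	0	21	0	36	22	14	86	0	26	2	0	7	0	0	13	0	0	1	180	42	1	0	113	11	11	0	1	519	1235	2
CT100_S1_R1	36	0	0	5	2	1	341	1845	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	738	16	0	0	0	0	0	0	0	0	0	1	3	0	0	3	7	0	0	0
CT100_S1_R2	53	0	0	0	0	1649	2	17	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	6	0	0	0	0	563	4	0	0	0	0	0	0	0	0	0	1	515	0	1	124	63	0	0	0
CT100_S1_R3	42	18	0	158	1	76	218	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	2205	1	0	0	0	0	0	0	0	24	0	160	41	1	3	12	28	0	0	7
CT100_S2_R1	135	30	2	2496	12	1	5	3	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	178	0	0	0	0	0	0	0	0	0	0	19	0	0	0	103	2	0	0	8
CT100_S2_R2	155	234	1438	159	10	15	0	630	31	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	7	1	0	0	0	0	0	0	0	0	0	72	1	0	1	245	1	0	0	0
CT100_S2_R3	2109	60	20	143	3	38	0	23	69	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	10	0	0	0	0	0	0	0	0	0	0	517	0	0	0	8	0	0	0	0
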
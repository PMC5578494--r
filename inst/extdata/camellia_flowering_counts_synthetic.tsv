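mature_id	kingdom	royal_jelly	honey	beebread	pollen
miR156a	plant	0	5	7230	6927
miR157a	plant	0	0	0	0
miR158a	plant	2	0	6931	7155
miR160a	plant	1	1	7065	6990
miR162a	plant	0	0	0	0
miR166a	plant	0	0	7342	7143
miR166g	plant	8	0	7069	7118
miR167a	plant	0	0	0	0
miR168a	plant	5	0	7041	6959
miR172a	plant	3	1	6945	7077
miR172c	plant	5	1	7003	7108
miR390a	plant	0	2	7233	7184
miR397a	plant	0	0	7042	7227
miR403	plant	0	2	6956	6981
miR824	plant	1	0	7045	7093
miR845a	plant	13	3	7174	7347
miR159a	plant	0	0	0	0
miR159b	plant	0	6	457	514
miR159c	plant	6	4	0	0
miR159d	plant	3	0	0	0
miR159e	plant	4	1	22	19
miR159f	plant	0	0	0	0
miR164a	plant	6	2	60	55
miR164b	plant	0	3	172	164
miR164c	plant	0	5	28	21
miR164d	plant	0	2	23	0
miR164e	plant	0	0	39	46
miR164f	plant	1	3	23	38
miR169a	plant	0	6	123	114
miR169b	plant	0	2	0	0
miR169c	plant	0	0	26	19
miR169d	plant	3	2	29	0
miR169e	plant	3	1	16	0
miR169f	plant	0	3	0	0
miR171a	plant	0	3	0	0
miR171b	plant	2	6	93	82
miR171c	plant	0	5	17	0
miR171d	plant	8	8	53	70
miR171e	plant	1	3	92	108
miR171f	plant	0	7	43	35
miR393a	plant	8	3	236	229
miR393b	plant	11	7	32	27
miR393c	plant	3	3	20	25
miR393d	plant	6	1	86	69
miR393e	plant	4	2	0	0
miR393f	plant	0	2	0	0
miR394a	plant	0	15	0	0
miR394b	plant	0	2	130	144
miR394c	plant	0	7	0	0
miR394d	plant	13	7	0	0
miR394e	plant	5	0	0	0
miR394f	plant	0	3	208	205
miR396a	plant	0	5	73	59
miR396b	plant	0	6	104	98
miR396c	plant	2	6	512	567
miR396d	plant	0	3	427	444
miR396e	plant	1	2	0	0
miR396f	plant	6	3	0	0
miR398a	plant	0	1	0	0
miR398b	plant	0	0	171	172
miR398c	plant	8	0	1320	1398
miR398d	plant	3	3	0	0
miR398e	plant	0	1	191	240
miR398f	plant	0	11	0	0
miR408a	plant	0	1	127	114
miR408b	plant	1	8	14	0
miR408c	plant	3	1	88	90
miR408d	plant	0	6	0	0
miR408e	plant	2	2	79	61
miR408f	plant	3	4	41	49
miR827a	plant	0	2	0	0
miR827b	plant	0	11	0	0
miR827c	plant	0	3	48	46
miR827d	plant	0	8	177	191
miR827e	plant	1	4	75	58
miR827f	plant	7	5	0	0
miR858a	plant	0	2	70	69
miR858b	plant	2	3	20	0
miR858c	plant	0	5	0	0
miR858d	plant	8	0	63	69
ame-miR-8	animal	307	0	0	1
ame-miR-163	animal	57	3	0	1
ame-miR-264	animal	118	0	0	0
ame-miR-340	animal	285	4	0	0
ame-miR-415	animal	54	0	0	4
ame-miR-451	animal	382	2	3	0
ame-miR-615	animal	353	1	1	0
ame-miR-704	animal	297	2	0	0
ame-miR-731	animal	431	0	0	0
ame-miR-745	animal	49	3	0	0
ame-miR-809	animal	0	2	0	0
ame-miR-867	animal	0	3	0	6
ame-miR-968	animal	41	0	0	0
ame-miR-984	animal	45	0	0	0
ame-miR-1010	animal	0	0	0	3
ame-miR-1013	animal	0	1	0	0
ame-miR-1032	animal	298	1	0	0
ame-miR-1056	animal	0	4	0	0
ame-miR-1071	animal	370	0	0	0
ame-miR-1131	animal	0	0	0	0
ame-miR-1181	animal	0	1	0	0
ame-miR-1322	animal	175	1	0	0
ame-miR-1343	animal	181	0	0	0
ame-miR-1348	animal	0	1	0	3
ame-miR-1410	animal	0	8	0	0
ame-miR-1470	animal	244	0	4	0
ame-miR-1525	animal	2	3	2	0
ame-miR-1557	animal	133	3	1	0
ame-miR-1590	animal	5	1	0	0
ame-miR-1596	animal	102	0	2	0
ame-miR-1605	animal	71	0	0	0
ame-miR-1629	animal	32	1	0	0
ame-miR-1664	animal	0	1	0	0
ame-miR-1727	animal	0	0	0	0
ame-miR-1824	animal	104	0	0	3
ame-miR-1825	animal	0	3	2	0
ame-miR-1897	animal	343	5	2	0
ame-miR-2006	animal	133	4	0	0
ame-miR-2014	animal	0	1	0	1
ame-miR-2078	animal	13	0	0	3
ame-miR-2141	animal	0	2	0	0
ame-miR-2225	animal	0	0	0	0
ame-miR-2231	animal	424	0	0	0
ame-miR-2244	animal	391	2	2	0
ame-miR-2276	animal	0	1	1	0
ame-miR-2292	animal	451	5	0	0
ame-miR-2318	animal	93	0	3	2
ame-miR-2349	animal	160	1	0	2
ame-miR-2357	animal	22	1	0	0
ame-miR-2593	animal	0	0	0	0
ame-miR-2604	animal	37	1	0	0
ame-miR-2661	animal	95	0	0	0
ame-miR-2690	animal	0	1	5	2
ame-miR-2796	animal	0	2	0	2
ame-miR-2867	animal	134	2	0	0
ame-miR-2883	animal	26	0	0	0
ame-miR-2889	animal	11	0	0	0
ame-miR-2890	animal	75	0	0	0
ame-miR-2968	animal	88	0	0	0
ame-miR-2971	animal	3	6	0	0
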
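mature_id	kingdom	royal_jelly	honey	beebread	pollen
miR156a	plant	7	6	6920	6840
miR157a	plant	6	6	7037	7063
miR158a	plant	3	4	6981	6891
miR160a	plant	0	4	7126	7061
miR162a	plant	0	4	7054	7021
miR166a	plant	0	2	7115	7054
miR166g	plant	0	1	7094	7029
miR167a	plant	1	0	7041	7053
miR168a	plant	4	5	6962	7078
miR172a	plant	0	10	6952	6962
miR172c	plant	11	4	6975	6933
miR390a	plant	2	3	7132	7153
miR397a	plant	0	3	7317	7104
miR403	plant	5	2	7105	7015
miR824	plant	4	2	7021	7082
miR845a	plant	0	5	6978	7051
miR159a	plant	3	0	0	0
miR159b	plant	4	4	15	14
miR159c	plant	0	7	46	45
miR159d	plant	0	5	0	0
miR159e	plant	4	3	23	26
miR159f	plant	4	3	15	17
miR164a	plant	2	1	0	0
miR164b	plant	4	4	97	77
miR164c	plant	0	6	54	51
miR164d	plant	0	0	0	0
miR164e	plant	1	3	15	0
miR164f	plant	1	1	860	911
miR169a	plant	0	2	50	46
miR169b	plant	2	10	0	0
miR169c	plant	0	1	96	82
miR169d	plant	0	7	16	17
miR169e	plant	8	0	14	15
miR169f	plant	1	4	116	94
miR171a	plant	0	2	45	35
miR171b	plant	0	1	0	0
miR171c	plant	1	4	0	0
miR171d	plant	0	1	6	0
miR171e	plant	7	0	14	24
miR171f	plant	3	4	0	0
miR393a	plant	5	5	0	0
miR393b	plant	0	1	10	0
miR393c	plant	2	2	36	36
miR393d	plant	0	3	22	23
miR393e	plant	10	3	3	0
miR393f	plant	0	1	20	16
miR394a	plant	0	4	63	57
miR394b	plant	0	5	38	39
miR394c	plant	1	4	5	8
miR394d	plant	1	9	0	0
miR394e	plant	6	3	76	61
miR394f	plant	0	4	31	34
miR396a	plant	3	4	0	0
miR396b	plant	0	3	12	0
miR396c	plant	11	2	37	19
miR396d	plant	0	1	20	11
miR396e	plant	0	2	40	48
miR396f	plant	1	0	12	14
miR398a	plant	0	4	0	0
miR398b	plant	4	3	0	0
miR398c	plant	1	4	0	0
miR398d	plant	0	8	0	0
miR398e	plant	2	3	16	10
miR398f	plant	0	2	0	0
miR408a	plant	7	0	0	0
miR408b	plant	0	4	0	0
miR408c	plant	9	2	50	49
miR408d	plant	0	0	13	13
miR408e	plant	0	2	48	62
miR408f	plant	1	5	16	12
miR827a	plant	0	3	49	49
miR827b	plant	13	5	286	277
miR827c	plant	0	0	0	0
miR827d	plant	0	11	27	21
miR827e	plant	0	7	162	169
miR827f	plant	0	1	133	142
miR858a	plant	0	2	12	10
miR858b	plant	0	1	0	0
miR858c	plant	1	1	0	0
miR858d	plant	10	2	0	0
ame-miR-8	animal	0	0	0	0
ame-miR-163	animal	319	3	0	0
ame-miR-264	animal	186	2	0	3
ame-miR-340	animal	437	1	0	0
ame-miR-415	animal	296	1	0	0
ame-miR-451	animal	103	2	1	0
ame-miR-615	animal	0	7	0	0
ame-miR-704	animal	486	2	2	6
ame-miR-731	animal	61	0	0	0
ame-miR-745	animal	153	2	1	0
ame-miR-809	animal	0	1	0	3
ame-miR-867	animal	0	1	0	2
ame-miR-968	animal	259	2	0	0
ame-miR-984	animal	183	5	2	0
ame-miR-1010	animal	0	2	0	0
ame-miR-1013	animal	126	0	0	1
ame-miR-1032	animal	54	0	5	0
ame-miR-1056	animal	0	0	0	0
ame-miR-1071	animal	145	1	4	0
ame-miR-1131	animal	44	2	0	0
ame-miR-1181	animal	108	0	0	0
ame-miR-1322	animal	0	0	1	1
ame-miR-1343	animal	0	0	0	1
ame-miR-1348	animal	130	2	0	0
ame-miR-1410	animal	60	0	0	0
ame-miR-1470	animal	30	0	0	0
ame-miR-1525	animal	131	5	0	0
ame-miR-1557	animal	141	2	0	0
ame-miR-1590	animal	13	2	0	0
ame-miR-1596	animal	80	4	3	6
ame-miR-1605	animal	145	1	0	0
ame-miR-1629	animal	39	0	2	0
ame-miR-1664	animal	24	1	0	0
ame-miR-1727	animal	0	1	0	0
ame-miR-1824	animal	470	5	0	0
ame-miR-1825	animal	166	3	0	0
ame-miR-1897	animal	582	0	0	0
ame-miR-2006	animal	158	8	0	0
ame-miR-2014	animal	0	0	0	0
ame-miR-2078	animal	0	2	0	0
ame-miR-2141	animal	71	2	0	2
ame-miR-2225	animal	0	1	0	0
ame-miR-2231	animal	203	3	3	0
ame-miR-2244	animal	405	2	0	0
ame-miR-2276	animal	61	1	0	0
ame-miR-2292	animal	27	0	0	5
ame-miR-2318	animal	613	0	0	5
ame-miR-2349	animal	344	0	1	4
ame-miR-2357	animal	134	2	0	2
ame-miR-2593	animal	100	0	0	0
ame-miR-2604	animal	381	3	0	1
ame-miR-2661	animal	0	1	0	0
ame-miR-2690	animal	289	0	3	0
ame-miR-2796	animal	75	0	1	0
ame-miR-2867	animal	20	1	0	0
ame-miR-2883	animal	209	0	0	0
ame-miR-2889	animal	0	4	1	0
ame-miR-2890	animal	144	0	0	0
ame-miR-2968	animal	42	5	0	0
ame-miR-2971	animal	189	1	0	1
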
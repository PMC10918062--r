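mirna	control_1	control_2	control_3	restricted_1	restricted_2	restricted_3
sim-miR-0001	2398	2247	1348	1667	3537	3133
sim-miR-0002	159	184	137	167	270	220
sim-miR-0003	7855	8865	5204	1540	825	1886
sim-miR-0004	43	98	30	73	67	29
sim-miR-0005	129	172	186	698	931	762
sim-miR-0006	505	779	1006	1539	1194	1388
sim-miR-0007	2	4	3	6	6	6
sim-miR-0008	56	98	93	154	160	96
sim-miR-0009	190	318	52	164	262	171
sim-miR-0010	207	350	214	134	246	217
sim-miR-0011	436	570	468	531	484	443
sim-miR-0012	171	211	211	290	143	441
sim-miR-0013	156	134	85	170	123	164
sim-miR-0014	2907	5285	2609	2494	4529	2893
sim-miR-0015	20	41	19	56	38	36
sim-miR-0016	80	326	195	183	191	98
sim-miR-0017	2074	3277	1554	1263	1721	1508
sim-miR-0018	407	746	165	2908	2079	2412
sim-miR-0019	230	485	319	1776	1069	1225
sim-miR-0020	689	1211	645	4010	2645	1419
sim-miR-0021	592	879	496	167	165	82
sim-miR-0022	233	515	170	302	514	338
sim-miR-0023	984	1398	881	1940	1526	1880
sim-miR-0024	442	827	530	3245	2416	1574
sim-miR-0025	259	493	81	650	194	275
sim-miR-0026	22	80	34	25	11	9
sim-miR-0027	111	201	116	185	116	138
sim-miR-0028	59	62	73	64	64	93
sim-miR-0029	9	12	6	14	7	15
sim-miR-0030	106	134	78	49	52	64
sim-miR-0031	135	347	114	104	112	107
sim-miR-0032	2264	6371	3193	5246	5463	2617
sim-miR-0033	3302	4173	2395	2111	666	789
sim-miR-0034	2611	3011	1193	1746	1576	2325
sim-miR-0035	76	38	54	66	79	57
sim-miR-0036	18	20	15	86	73	75
sim-miR-0037	43	122	199	180	187	117
sim-miR-0038	2186	5678	1708	3345	3068	3462
sim-miR-0039	354	725	293	602	570	306
sim-miR-0040	1054	1212	652	980	996	896
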
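gene	control_1	control_2	control_3	restricted_1	restricted_2	restricted_3
gene00001	367	563	348	265	314	207
gene00002	3625	1709	1959	2142	2955	3113
gene00003	7489	6428	5994	8664	6711	10681
gene00004	84	111	51	68	97	49
gene00005	20	39	21	295	214	420
gene00006	1215	1217	3363	2261	2478	953
gene00007	42	48	48	35	70	66
gene00008	1265	958	748	3773	7431	6000
gene00009	2080	1995	2232	1533	3138	2480
gene00010	3	7	5	4	10	6
gene00011	456	322	182	248	411	344
gene00012	278	462	217	270	270	490
gene00013	42	24	14	26	37	43
gene00014	66	82	62	77	103	68
gene00015	1297	597	593	1496	1265	925
gene00016	597	329	731	303	717	529
gene00017	1025	1426	1004	617	2394	1119
gene00018	118	78	73	72	58	40
gene00019	18887	30940	19128	12900	22259	24599
gene00020	429	340	334	2781	2871	1604
gene00021	166	150	225	180	288	144
gene00022	200	94	131	671	563	997
gene00023	89	154	98	121	39	41
gene00024	85	158	85	448	355	279
gene00025	1020	1498	544	676	1510	717
gene00026	101590	156408	84482	79615	74498	111516
gene00027	101	51	129	109	114	128
gene00028	12	8	9	30	47	42
gene00029	306	401	281	1363	2550	2127
gene00030	55	50	29	47	71	93
gene00031	2404	2333	2031	2985	3895	2323
gene00032	73	81	142	614	792	930
gene00033	4182	6351	4578	12884	32683	29435
gene00034	522	405	437	535	195	611
gene00035	275	245	289	1087	2771	1325
gene00036	2012	1933	1445	1533	1726	1759
gene00037	202	149	74	69	93	158
gene00038	765	1505	775	167	161	143
gene00039	1	2	3	2	3	2
gene00040	616	517	500	495	802	960
gene00041	10411	7609	5138	4408	5554	7434
gene00042	1478	2766	1044	1419	1620	1173
gene00043	1502	2751	1438	1311	2452	2367
gene00044	2863	5673	2970	1671	3610	5142
gene00045	3435	2287	1767	1704	3546	1791
gene00046	6	18	9	10	11	7
gene00047	1043	540	512	527	1105	918
gene00048	564	634	950	808	992	698
gene00049	190	198	75	766	620	1240
gene00050	557	542	547	80	143	80
gene00051	27	33	24	17	15	19
gene00052	70	164	112	86	150	138
gene00053	437	617	262	22	93	114
gene00054	234	295	197	347	356	439
gene00055	113	180	94	64	196	61
gene00056	649	1984	1674	754	1134	1653
gene00057	1731	1495	1083	178	176	343
gene00058	1302	1111	555	1179	417	800
gene00059	543	380	417	319	203	277
gene00060	61	42	56	51	62	45
gene00061	97	83	74	47	170	43
gene00062	1321	1524	2064	1762	3053	1999
gene00063	55	83	59	36	28	96
gene00064	181	219	399	250	259	271
gene00065	130	178	81	83	163	94
gene00066	149	92	105	9	25	16
gene00067	17	29	22	22	16	14
gene00068	120	198	169	16	31	12
gene00069	1913	1481	1270	1285	1582	2643
gene00070	16995	16197	13666	15735	25626	16129
gene00071	18	30	35	20	24	27
gene00072	260	360	388	244	321	589
gene00073	325	505	385	230	319	178
gene00074	582	148	282	317	446	422
gene00075	1571	2631	1912	1118	3905	1277
gene00076	6	7	1	49	31	29
gene00077	163	115	106	64	133	113
gene00078	411	617	377	455	540	703
gene00079	678	842	604	348	870	825
gene00080	52	50	27	17	53	58
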
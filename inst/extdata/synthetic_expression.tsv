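gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16
g001	4940	15520	1970	16000	1450	9110	1970	2180	1406	1403	211	68	942	1472	1383	2037
g002	4250	9160	800	6330	4400	4150	15800	2310	275	601	365	579	230	598	174	1441
g003	3290	3280	4560	10880	5970	8970	3390	4890	3490	462	150	900	772	934	3240	281
g004	1120	3940	2800	4750	6560	15890	1080	2880	293	433	217	89	411	460	602	368
g005	1780	2660	6160	8360	15580	6470	4130	5170	1235	1941	202	375	191	198	1474	846
g006	9620	6590	7650	3940	8780	1700	2320	11800	755	2094	157	502	290	1593	1096	344
g007	38190	3160	2990	31560	9000	17940	14960	2150	243	4330	1100	463	298	589	304	197
g008	8100	9070	3900	1910	9850	9810	8860	7480	4829	337	241	509	3137	221	2050	1433
g009	3850	2020	8450	4220	6840	2680	1550	9960	659	592	823	1911	671	810	398	3041
g010	19620	4050	880	2810	2520	6310	5250	12150	76	290	102	1084	705	168	774	174
g011	9380	4050	3520	1500	3600	1730	2260	11350	1193	1644	280	114	768	198	440	543
g012	14250	29430	4220	4240	10200	1530	3760	1050	659	326	155	69	989	272	925	365
g013	11580	5360	820	17080	3440	7690	1440	9180	63	112	38	363	510	1261	531	489
g014	2030	19090	8330	2790	6930	12540	6590	5890	65	2716	355	870	760	566	830	302
g015	3250	5710	2630	24530	2160	1760	2680	5570	1416	1291	620	94	1687	382	422	225
g016	2410	5790	5390	7740	27140	15830	3380	2740	278	957	5247	3344	675	61	146	143
g017	11200	2030	12200	2930	3400	2470	1020	14010	2938	477	460	234	1852	986	158	528
g018	5850	16000	26390	10250	119270	680	750	1450	1331	160	56	1173	1729	58	132	726
g019	7290	27260	5250	5250	3180	4810	1200	14880	915	330	1511	298	1366	532	997	129
g020	13190	9650	9480	5560	16870	2300	2920	1740	425	538	1642	375	4524	117	818	4880
g021	1061	164	1508	127	63	2398	134	142	2310	16840	15290	10580	3840	5600	8450	9940
g022	1546	169	174	474	1879	522	76	5492	3290	20330	13970	27930	3020	2890	730	840
g023	739	259	2264	301	118	1345	384	439	11030	1570	2560	2580	4210	4600	4460	2890
g024	1016	2268	953	675	5419	247	65	199	8240	7890	7800	3110	2070	3670	860	9230
g025	792	940	712	339	168	2966	108	1554	7800	24320	3850	880	6260	25690	11750	2380
g026	671	424	1602	221	284	4212	433	1029	3250	3410	2670	31200	6970	1750	3220	1050
g027	916	199	3136	65	130	811	645	353	8380	4410	2310	12370	17790	6290	3960	9320
g028	276	354	188	751	139	584	114	302	4910	22690	1390	3820	14090	2660	7080	4340
g029	203	1694	863	170	611	642	333	169	820	6400	15830	1270	1010	4480	2310	720
g030	145	885	768	92	750	337	313	854	5560	1870	1560	4440	7810	83800	4840	4360
g031	201	1609	1002	1309	500	4588	5198	265	7440	25080	5450	7230	1810	10330	2560	26480
g032	797	510	2454	71	876	63	57	187	35960	6630	380	4360	840	13490	18730	13320
g033	600	134	501	1515	1415	218	545	1110	2440	8550	1000	17020	2340	3660	2170	4680
g034	168	252	485	154	388	338	165	650	6690	4680	6480	4250	8320	35430	49070	2250
g035	86	354	81	755	1826	476	361	134	3790	2880	3540	2150	12950	660	15310	3430
g036	577	396	439	693	835	376	501	714	8140	8210	3820	330	7100	5900	1770	3740
g037	119	615	499	1138	246	125	396	34	5240	13100	1880	51350	5220	3220	4390	1910
g038	1101	4442	60	1041	668	1355	336	505	2030	9490	14080	3610	5330	5640	1150	3480
g039	531	135	1710	279	503	673	140	317	9480	6770	1950	12620	1110	5830	13650	3790
g040	228	1266	1073	125	599	91	966	352	2600	7260	5860	7690	850	4470	8220	2950
g041	944	342	828	1500	463	1279	1103	4949	132	384	1586	13473	207	1075	1803	2019
g042	1262	166	965	272	120	917	264	1410	89	271	1488	265	762	1084	234	417
g043	332	953	852	1974	181	547	453	351	1387	193	984	343	211	702	1731	1898
g044	1110	1305	829	691	1553	119	665	1159	1290	1319	3839	291	265	767	947	183
g045	868	657	1180	1072	2526	133	725	782	348	1748	298	223	248	610	362	262
g046	1378	292	508	544	432	504	120	1775	627	129	208	57	203	2422	1663	145
g047	134	198	528	2713	1843	232	1262	1626	1786	1490	47	33	575	85	4105	430
g048	1348	300	187	480	182	545	68	569	211	101	184	309	281	384	744	405
g049	1405	1698	897	131	565	7231	330	212	380	110	1008	517	868	1094	118	626
g050	9163	304	243	796	648	334	198	107	153	128	583	342	177	9504	665	202
g051	98	145	2477	655	1234	188	1062	232	180	254	87	144	563	339	827	844
g052	566	624	1311	544	251	1010	431	1176	595	274	210	236	1176	755	5261	63
g053	608	641	101	196	973	299	2171	419	238	231	1343	530	489	512	974	310
g054	193	428	332	4312	137	673	806	1150	740	305	982	1068	1219	522	244	1245
g055	787	334	346	2032	1013	1889	156	261	213	2970	62	798	735	777	371	732
g056	916	787	630	143	465	1772	380	616	340	300	513	864	175	114	3131	154
g057	1796	1560	675	857	880	597	686	821	359	651	491	2952	996	804	612	2224
g058	451	109	74	200	201	585	634	179	265	1187	164	571	485	905	97	880
g059	292	201	87	374	931	2809	331	448	350	239	201	1798	265	409	1187	705
g060	74	327	370	452	299	105	960	676	326	1236	346	312	918	623	1229	232
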
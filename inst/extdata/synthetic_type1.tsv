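feature_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24
t1_f01	-0.9332	-1.6792	-0.9622	1.0159	-1.7978	-1.9831	-2.3356	-1.2584	-0.8133	-0.4911	0.5198	-1.9899	2.5186	2.0388	1.4479	2.0271	0.7124	-0.7542	2.4565	1.3796	2.3811	3.2495	2.471	1.5227
t1_f02	-0.2227	0.7856	-2.1245	-0.9467	-2.5902	0.613	-0.8738	0.0772	-0.4092	-0.4003	-1.5814	-1.5855	1.2921	1.3238	2.7102	1.034	1.4612	0.5057	-0.4815	0.776	1.189	1.7895	0.5634	2.5544
t1_f03	-1.8398	-1.5683	-1.2721	-0.2216	-0.8448	-2.0737	-1.1027	-1.4186	0.0785	-1.3991	-3.3246000000000002	-0.6756	0.8092	0.3964	0.4226	0.0355	0.9113	2.4138	-0.4946	1.3648	1.0333	2.2194	0.5848	-0.2037
t1_f04	-0.095	0.3866	0.0501	-2.5383	-0.8513	0.0679	-1.3642	-2.3523	-2.2491	-3.3467	-1.8826	-0.9677	1.5705	1.5861	1.0287	0.3278	1.5492	0.7847	2.3632	-0.1591	0.3546	3.2301	-0.5227	2.6731
t1_f05	-1.8853	-1.2792	-0.3083	-2.3831	-3.1083	-0.1921	-1.9143	0.3076	-2.235	-0.545	0.6412	-0.7861	2.5054	1.4757	1.1897	-0.2807	0.0014	2.9616	1.1075	1.9215	1.8634	-0.1392	1.9713	2.7452
t1_f06	0.1668	1.0841	-0.4912	0.4177	0.2232	0.1983	-0.9408	-0.6748	1.6759	-1.8308	1.4347	-1.1157	0.4999	0.5036	-0.1811	-2.117	-0.237	0.7968	0.7901	-0.3293	1.0259	1.2023	0.7379	1.0753
t1_f07	-1.5271	2.9077	1.2542	-0.6351	2.1861	1.8634	-0.6675	0.7035	0.143	-0.207	-1.0472	-2.4934	0.6591	0.4445	-1.1108	-1.2871	-1.4761	-0.6787	-1.5194	0.0107	0.0751	-0.4586	1.1076	0.013
t1_f08	-2.382	0.3066	0.0351	-0.0435	-0.2724	-0.5157	-0.2072	-1.3779	-0.9603	0.0497	1.08	-1.4972	-1.1207	-0.4323	-1.0086	0.2139	0.7309	-0.7138	0.9117	-0.1039	-0.5928	-0.4304	0.7831	0.9821
t1_f09	0.1029	0.104	-0.8485	-0.8219	-0.7083	0.5056	0.9971	-0.1274	0.7843	0.9533	0.6426	-0.2175	-0.4226	-0.4155	-0.158	0.4108	0.4028	-0.8227	-0.7576	0.3734	-0.2776	0.9826	-0.1026	-0.9431
t1_f10	0.9173	1.6217	-1.5702	-0.2037	1.2451	-0.0345	0.3499	-1.7581	-0.8219	-1.3165	-1.1303	-0.9092	1.5171	-0.6081	-0.6267	0.2674	0.0756	-0.9244	1.2753	-0.4418	1.1275	0.9906	1.6677	0.1144
t1_f11	-0.215	0.4188	1.0477	0.7397	0.8234	-2.2166	-0.74	-1.0087	1.3749	-0.1438	-2.0629	-0.2184	0.0672	1.1788	0.8703	-1.0888	0.2887	0.5285	0.7837	0.1057	0.247	0.1045	-0.0888	-1.7527
t1_f12	-1.0905	0.4998	0.9435	1.5145	0.6025	0.2502	0.0993	0.3252	-0.2712	-1.0765	-0.9885	1.9106	1.3642	0.1683	-0.0575	0.9756	-0.6134	1.3652	0.0495	0.9097	0.1581	-0.8534	-0.5768	0.3935
t1_f13	1.4499	-0.7981	-0.6548	-0.2102	-0.351	-0.6926	-2.5046	0.0116	0.7883	1.6971	0.5868	-0.6361	-0.9415	-0.1796	-1.2456	0.7541	1.4044	-1.1085	1.3986	0.1175	-0.7115	0.612	0.2379	-1.4012
t1_f14	-0.5695	0.2839	-0.2861	1.5892	0.6335	-0.754	1.0739	-0.023	-0.5114	0.0552	-0.9956	0.0659	-0.9437	-0.7849	-0.452	-0.5386	1.4093	0.299	0.2275	0.1918	0.6982	-0.9877	0.866	0.0542
t1_f15	-0.5909	-1.3447	0.5286	1.3114	-0.5618	1.1272	1.203	0.7616	1.0885	-0.9419	-1.1151	-0.9	0.949	0.2481	0.0571	-0.4347	-1.5469	0.8103	-0.2204	-0.3755	-0.0896	-1.5337	-1.9072	-0.6997
t1_f16	0.3683	1.4378	-0.9772	1.2826	1.7164	-1.0716	-0.5224	-0.52	-2.3636	0.0204	0.2741	-1.2609	-1.4793	0.202	-1.7833	-1.4088	1.7689	1.9728	-0.904	0.6393	-1.0595	0.8332	-1.7934	-0.0637
t1_f17	0.146	1.3884	0.1379	-0.4887	0.1625	-0.2193	1.5808	0.7216	-0.5182	-1.1683	0.3358	-0.2016	0.8666	2.004	0.075	2.388	-0.4671	0.4426	-1.9232	-0.4599	-0.8505	0.3455	-0.3204	1.9769
t1_f18	-0.9685	-0.4171	-2.0977	1.1009	0.0505	-2.4838	2.8022	1.7518	-0.9171	1.2115	-0.3832	1.1468	0.2543	-0.0565	-0.7551	-0.0741	-0.91	0.2201	-0.3909	0.0412	-1.2718	-1.0538	1.5169	0.2689
t1_f19	-2.9016	-0.8076	1.4105	0.9877	-0.1882	1.2107	0.5591	1.2549	-0.7075	-1.1566	0.0363	-0.0455	-0.2075	0.8918	0.7678	-0.514	-0.3922	-0.0376	0.1389	-2.2397	-0.7651	1.5117	0.7274	0.9349
t1_f20	-0.5781	0.346	0.2588	0.1624	-0.3531	0.2286	0.1648	-0.353	-0.1623	0.0805	0.1617	-0.9687	-1.1126	1.0728	-0.8542	-1.223	0.2478	-0.2679	-0.9305	0.9313	1.6332	0.9943	0.2219	1.1628
t1_f21	3.0196	-0.2279	1.0029	-0.2652	0.8262	0.5577	-0.8806	-1.3401	-0.7122	-1.5895	0.1633	-0.7193	-0.7352	-0.222	-0.8238	-0.3729	-0.4828	-2.332	0.268	0.7544	1.7706	0.1992	0.241	0.0185
t1_f22	-0.5182	0.1398	-1.4612	-1.4124	-0.8615	-0.8775	-0.5161	-0.1886	-0.0437	0.7987	0.9819	0.719	-1.8329	0.2524	1.0828	0.3245	0.9585	-0.5164	-0.9466	-0.405	1.2022	-3.019	-1.6514	-0.6922
t1_f23	1.1082	1.241	0.2554	-1.2232	1.0054	1.3601	1.4436	-2.1797	0.5546	1.3241	-0.0369	-1.0918	0.0995	-0.2532	0.9952	0.8558	0.2435	0.9718	-0.9453	-0.2846	-0.2533	0.245	0.2053	0.8449
t1_f24	0.8038	-0.6119	-0.7144	-0.3619	1.3704	-0.3809	-2.6537	-0.4625	-0.7352	-0.2959	1.018	-1.0435	0.7514	-0.6316	-0.6339	-1.1167	0.2211	-0.4475	-1.3203	2.1512	0.2272	1.3781	-0.6728	0.6158
t1_f25	0.772	2.1785	-0.3227	0.8588	-0.8355	1.0452	0.7106	0.111	-1.4851	0.9924	1.2873000000000001	1.0207	0.6876	0.2625	-0.1477	0.3351	-0.7314	-1.9982	-2.581	1.1959	0.0333	-0.4254	0.4926	-0.6088
t1_f26	0.223	-0.7219	-1.0569	0.3393	1.7078	-0.4502	-0.9196	0.7555	-0.6058	-0.9579	-0.1286	-0.7619	-0.5496	-0.1158	0.8308	-1.2934	1.5115	-0.2607	-0.1618	0.4531	1.0656	1.8578	0.8044	0.1317
t1_f27	0.489	1.3996	0.4418	0.6137	1.4563	0.9246	0.0781	1.5815	1.1913	-0.0347	-0.4591	0.1158	0.6958	0.6051	0.7048	-0.0075	-1.4356	-0.0168	0.755	-1.0272	0.0861	1.0192	1.0076	1.3643
t1_f28	-0.086	0.9298	0.1511	-1.0346	0.8751	-1.391	-0.0126	-0.1922	1.029	1.329	-0.1141	-0.2052	1.1126	-0.3141	-1.1485	-0.7624	-0.6767	-0.8982	0.56	1.0358	0.15	-0.1995	-1.2727	0.0244
t1_f29	-0.0055	-0.4263	-0.5709	-0.2125	1.355	2.6583	-0.4494	-0.1888	-0.7649	-0.6156	-0.5562	0.0566	0.4301	-0.5902	-2.0664	-1.3872	-2.1565	0.4209	0.1159	-0.5375	0.5333	0.2515	0.5173	-0.2788
t1_f30	-0.2034	-0.9368	-1.4807	-0.7275	-0.5894	0.3509	0.3036	2.8869	0.2336	-1.2653	0.4084	-0.3921	1.161	-0.2376	0.1199	-0.71	0.321	-0.0845	0.32	-1.3788	0.2007	1.6916	-1.5158	-1.1924
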
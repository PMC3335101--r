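feature_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24
t2_f01	-2.0139	-1.7079	-1.3016	-1.5314	-1.1571	-2.5704	-0.8304	-1.0887	-0.135	-2.8835	-0.8399	-2.7657	2.109	1.6204	2.4837	2.1128	1.6885	1.5099	1.0365	2.1906	1.2187	-0.4399	1.1531	1.968
t2_f02	0.9736	-0.7306	-0.544	-0.0393	-0.7608	-0.1748	-1.4654	-1.6862	-0.2549	-2.5955	-1.2931	-2.7829	0.282	1.5776	-0.0015	2.1376	1.4634	2.4469	1.1124	2.29	-0.5954	0.4549	1.1945	0.7782
t2_f03	0.1143	-1.2995	-1.0951	-1.2404	-3.3524	-0.3614	-1.4627	-0.2444	0.4232	-1.1057	-0.4978	-0.9331	1.1047	2.2714	2.0671	0.7945	1.453	1.8548	0.9316	0.7057	1.4315	-0.4823	-0.1384	2.6666
t2_f04	-1.0833	-2.8949	-0.5099	-1.9289	-1.8761	-1.174	0.0388	-1.8671	-1.7644	-1.6832	-1.932	-2.0637	-1.0268	2.6051	0.8689	0.7568	0.4764	0.7974	0.2936	2.6089	2.7527	1.41	0.2281	1.443
t2_f05	-1.5785	-0.8691	-0.3869	-0.8408	0.3786	-1.9862	-2.2833	-3.9042	-1.0856	-0.6665	-1.7059	0.2648	1.3208	1.3991	2.0086	1.9199	0.6163	1.3366	0.8236	2.9547	2.4034	1.3664	1.0638	0.5962
t2_f06	-0.2202	0.2283	-1.1538	-1.6951	-0.5667	1.8593	-0.8081	0.9204	-0.6719	-1.0963	-0.6123	0.2176	1.2461	-1.1149	1.1954	-2.843	-1.553	0.0143	0.1244	-0.1535	-0.0064	0.016	0.5449	-0.4344
t2_f07	-2.2312	-0.0753	1.1072	-0.3061	2.2727	1.633	1.3421	-0.9233	-1.8173	0.1411	1.9164	0.3543	-1.1682	-0.9683	-0.0968	-0.3705	1.1577	1.2183	-0.4091	-0.2287	-0.0827	-0.9856	-0.5988	-0.4162
t2_f08	0.3558	0.7752	-0.2413	-0.5083	0.2847	-0.5672	0.1463	1.0864	0.3192	-1.0897	0.6927	0.0614	-0.9356	0.117	-0.3611	-0.091	0.4047	-1.7516	-0.5918	-0.3793	0.3682	1.5237	1.5033	1.4019
t2_f09	-2.2891	0.4819	-1.3532	0.3125	3.273	1.4251	-1.5787	-1.1978	0.1149	0.2849	-0.9689	0.8083	0.0649	0.719	-0.9035	0.5769	-2.5753	1.014	-0.9156	-0.221	0.8003	0.5372	1.8918	-0.3377
t2_f10	-0.8385	0.2629	0.6866	0.2433	-0.2751	-0.1191	1.1842	0.5349	-0.006	-1.4112	0.5368	-0.3655	-1.1035	1.7174	0.7989	0.8097	-0.8049	-0.542	-0.1108	-1.4136	0.8173	-1.7575	-1.6139	1.5599
t2_f11	-0.1544	-0.7841	-0.5463	0.1418	-1.6178	0.8818	-1.3007	-1.5195	0.1733	0.4648	0.4438	-0.9043	0.468	-0.0733	0.1897	0.6551	-0.0757	1.1639	0.7377	-0.6258	0.3499	-1.6898	-1.1655	-0.4795
t2_f12	1.0279	0.6779	1.3303	-0.0727	1.0165	-2.0499	1.7333	-0.4864	-0.79990000000000006	0.2136	-0.9196	-1.2301	-0.7166	1.4453	-1.4125	1.5663	1.0175	2.2187	-0.453	-0.3973	0.6253	-1.511	0.5522	-0.9294
t2_f13	-1.6998	-1.5358	-0.8995	-0.6587	0.9765	0.7414	-2.2298	1.5707	0.3286	-0.1289	0.0553	-0.0186	-0.2656	-0.5204	0.5908	0.8664	0.6513	0.642	-0.4289	-2.0417	-1.0531	0.0018	0.7923	1.8418
t2_f14	-0.0432	1.6123	1.1527	-0.3617	-0.4588	0.1513	1.6214	0.3651	0.1877	2.0868	1.3875	0.214	0.1477	-0.2609	-0.6975	1.122	1.8813	-0.5762	-0.5447	-1.4956	-0.2204	0.2313	-0.9847	-0.1099
t2_f15	-0.738	-1.7212	0.7189	-0.7881	-1.5142	-1.2846	1.0018	2.3077	1.666	-0.4726	0.6072	-1.1142	-1.2035	0.9184	-0.2593	-0.4598	1.3302	-0.5038	1.8185	0.5103	0.0334	0.8043	-0.1754	1.0993
t2_f16	-0.4655	-1.2151	0.8269	-0.0196	0.1392	-0.3697	-0.7471	0.9252	-0.2006	-1.2792	1.1973	0.6953	-0.2709	0.7925	2.638	-0.7202	-1.3904	-0.4576	-0.0391	0.1393	1.5656	-1.1875	-0.031	0.6303
t2_f17	0.5343	-1.2799	0.15310000000000001	-0.7626	-1.3088	0.3352	-0.295	-0.9286	-0.1482	-0.1923	2.5786	0.1584	0.4639	0.8973	0.1511	1.6001	1.3746	0.7893	-0.8143	0.8145	0.614	0.6026	0.9466	-0.2877
t2_f18	1.0425	0.8563	-0.9116	0.2914	0.0681	-0.2892	0.8586	-0.3595	-0.3741	1.4299	-0.0371	-1.4253	-0.5647	-0.5367	1.1076	-0.1877	-2.0081	-1.7456	-0.2577	-0.0916	-0.9071	-0.0317	0.9876	-0.3493
t2_f19	0.6445	-0.7489	2.288	0.384	1.41	0.6313	0.5191	1.7244	0.7501	0.0794	1.3257	1.5297	0.3358	0.3278	-0.6241	-0.5973	0.6469	-1.1289	-0.3677	-0.9697	0.8056	0.1172	-0.1321	-0.5416
t2_f20	-0.3187	-2.3593	-0.0616	1.3697	0.2406	1.4928	-0.1498	-0.34	0.6468	-1.1044	1.0644	-0.5623	0.5424	-0.8617	-1.02	0.165	0.2648	-0.5843	0.1263	1.9093	1.7155	-0.7191	0.4265	-0.3019
t2_f21	-0.9719	0.3131	-0.0255	1.1145	0.2445	-0.2368	0.4927	0.8338	0.5337	-0.0935	-1.6622	-1.4557	-0.0264	-0.6995	-0.9938	-0.7016	0.2745	-1.0245	-1.1454	1.0753	0.8052	0.4831	0.7573	0.4603
t2_f22	-1.7251	0.5818	0.0893	0.227	0.0533	0.312	1.2905	-1.9918	1.4394	-1.7267	-0.4511	-0.9767	0.5921	-2.8465	1.1049	0.6313	0.6323	0.1553	-0.5107	0.0544	-0.4011	-0.9634	-1.5283	0.078
t2_f23	-0.1578	-0.7953	1.1832	-1.4401	-0.2564	-0.036	0.853	-1.9187	-0.6369	0.1551	0.7058	0.8233	-0.1122	-0.1845	-0.9256	1.3205	-0.6753	-0.6373	0.0935	-0.2822	-0.7925	-1.046	-0.4097	2.7837
t2_f24	-1.2754	0.1913	1.3902	1.1274	-0.7085	-1.2822	1.3806	-0.8697	-1.1435	0.1804	-0.7501	0.6283	-0.2471	-1.0191	-2.0939	-0.285	-1.5058	-1.4547	0.7584	1.2278	2.4705	0.6165	-0.3121	1.0586
t2_f25	-0.692	-0.4535	0.1669	0.4207	0.5021	0.2158	-0.6712	0.2758	-0.1521	-1.019	0.3729	2.5094	1.2533	-0.8387	0.2816	0.5804	0.4039	-0.4405	-1.2294	-0.1216	2.316	0.6108	-1.4296	0.0022
t2_f26	0.6825	-0.513	0.6109	0.44	0.9875	0.2918	-0.2522	-0.3055	2.4068	-0.3622	-0.6724	-0.555	1.8605	0.2646	0.4613	0.4554	0.4901	-0.8303	0.9231	-1.2003	1.0727	-0.4195	1.0769	0.994
t2_f27	-0.6627	2.3111	-0.8015	-0.1039	-0.5957	-0.6209	-0.7806	0.267	0.8371	-0.8217	0.463	0.4117	0.584	0.634	-0.897	0.7865	-0.659	2.0783	-0.231	-1.312	-0.6605	0.3126	-1.2682	-1.1217
t2_f28	0.4601	0.9311	2.4683	0.1327	0.0716	-0.222	-0.6584	0.8805	0.7275	-0.2111	-1.8257	-0.6074	0.4809	-0.6022	-0.7738	0.5889	0.0534	0.7339	-0.4829	0.7597	-0.25	-1.0647	1.1366	0.2014
t2_f29	0.3918	-0.1687	-0.5546	-0.8127	-2.6577	-0.5933	-0.9936	-0.4793	0.1619	-1.0767	-0.0195	0.1195	0.1631	-0.1489	-1.3137	-2.9182	0.8374	1.3655	-0.2409	-1.0545	0.0175	1.1684	-0.0037	0.6779
t2_f30	0.6397	1.2225	-0.5915	1.3185	-1.7779	-0.3966	0.6788	1.0463	-0.4159	1.119	-2.3416	1.0043	1.2804	0.1609	-0.7368	-1.1389	1.029	0.6793	0.1508	-1.0609	1.3217	-0.1161	1.8022	-1.9169
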
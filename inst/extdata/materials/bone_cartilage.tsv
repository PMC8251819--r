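# medium: bone_cartilage
# density_g_cm3: 1.1
# composition: H=0.096 C=0.099 N=0.022 O=0.744 Na=0.005 P=0.022 S=0.009 Cl=0.003
# columns: energy[MeV] mu_photo mu_compton mu_pair [cm^2/g] s_col s_rad [MeV cm^2/g]
energy_MeV	mu_photo	mu_compton	mu_pair	s_col	s_rad
0.01	6.09845	0.210855	0	22.4073	3.95133e-05
0.010864604	4.7553	0.210187	0	21.0085	4.43781e-05
0.011803962	3.70797	0.209467	0	19.6959	4.98418e-05
0.012824537	2.89131	0.208693	0	18.4646	5.59782e-05
0.013933352	2.25451	0.207859	0	17.3101	6.28702e-05
0.015138035	1.75797	0.206964	0	16.2281	7.06106e-05
0.016446875	1.37079	0.206003	0	15.2144	7.9304e-05
0.017868878	1.06888	0.204973	0	14.2651	8.90677e-05
0.019413829	0.833462	0.203868	0	13.3764	0.000100034
0.021092356	0.649897	0.202686	0	12.5448	0.000112349
0.022916009	0.50676	0.201422	0	11.7669	0.000126182
0.024897337	0.395149	0.200073	0	11.0395	0.000141717
0.02704997	0.308119	0.198634	0	10.3595	0.000159165
0.029388721	0.240258	0.197102	0	9.72423	0.000178761
0.031929682	0.187342	0.195473	0	9.13084	0.000200769
0.034690335	0.146081	0.193744	0	8.57681	0.000225488
0.037689675	0.113908	0.191911	0	8.05972	0.000253249
0.040948339	0.08882	0.189973	0	7.57731	0.000284429
0.044488748	0.0692578	0.187927	0	7.12743	0.000319447
0.048335263	0.0540042	0.185771	0	6.70805	0.000358776
0.052514349	0.04211	0.183504	0	6.31729	0.000402948
0.05705476	0.0328355	0.181126	0	5.95334	0.000452558
0.061987737	0.0256037	0.178637	0	5.61452	0.000508276
0.067347221	0.0199646	0.176038	0	5.29927	0.000570854
0.073170089	0.0155675	0.173331	0	5.00608	0.000641136
0.079496403	0.0121388	0.170519	0	4.73357	0.000720071
0.086369694	0.00946532	0.167605	0	4.48043	0.000808725
0.093837252	0.00738063	0.164594	0	4.24543	0.000908293
0.10195046	0.00575509	0.161492	0	4.02743	0.00101367
0.11076513	0.00448756	0.158304	0	3.82534	0.00110789
0.12034193	0.0034992	0.155038	0	3.63816	0.00121086
0.13074674	0.00272852	0.151702	0	3.46495	0.0013234
0.14205116	0.00212758	0.148304	0	3.30482	0.00144641
0.15433296	0.00165899	0.144853	0	3.15694	0.00158085
0.16767664	0.00129361	0.141357	0	3.02054	0.00172778
0.18217403	0.0010087	0.137826	0	2.89491	0.00188837
0.19792487	0.000786536	0.13427	0	2.77936	0.00206389
0.21503753	0.000613305	0.130698	0	2.67326	0.00225572
0.23362976	0.000478228	0.127118	0	2.57603	0.00246538
0.25382949	0.000372901	0.123539	0	2.4871	0.00269452
0.27577568	0.000290771	0.11997	0	2.40597	0.00294497
0.29961936	0.00022673	0.116417	0	2.33215	0.00321869
0.32552457	0.000176794	0.112887	0	2.26518	0.00351786
0.35366955	0.000137856	0.109387	0	2.20465	0.00384483
0.38424796	0.000107494	0.105922	0	2.15016	0.00420219
0.41747019	8.38191e-05	0.102496	0	2.10132	0.00459276
0.45356482	6.53584e-05	0.0991141	0	2.05749	0.00501964
0.49278022	5.09636e-05	0.095779	0	2.01719	0.0054862
0.53538619	3.97391e-05	0.0924937	0	1.98136	0.00605664
0.58167589	3.09868e-05	0.0892606	0	1.94968	0.00670069
0.63196782	2.41621e-05	0.0860818	0	1.92188	0.00741323
0.686608	1.88405e-05	0.0829587	0	1.8977	0.00820155
0.7459724	1.4691e-05	0.0798929	0	1.87688	0.00907368
0.81046947	1.14554e-05	0.0768856	0	1.85916	0.0100386
0.88054298	8.93239e-06	0.0739379	0	1.84433	0.0111061
0.95667507	6.96508e-06	0.0710506	0	1.83215	0.0122871
1.0393896	5.43106e-06	0.0682249	7.72739e-07	1.82241	0.013599
1.1292556	4.2349e-06	0.0654616	4.76611e-06	1.81491	0.0150578
1.2268915	3.30218e-06	0.0627617	9.10475e-06	1.80945	0.0166731
1.332969	2.57489e-06	0.060126	3.19875e-05	1.80585	0.0184616
1.448218	2.00779e-06	0.0575554	6.23466e-05	1.80393	0.0204421
1.5734315	1.56558e-06	0.0550508	0.000122858	1.80353	0.0226349
1.7094711	1.22077e-06	0.052613	0.000209691	1.80448	0.025063
1.8572726	9.51903e-07	0.0502427	0.000304031	1.80666	0.0277516
2.0178531	7.42251e-07	0.0479408	0.000407433	1.8099	0.0307235
2.1923175	5.78774e-07	0.0457076	0.00052763	1.8141	0.0339663
2.3818661	4.51302e-07	0.0435438	0.00065822	1.81913	0.0375514
2.5878032	3.51905e-07	0.0414496	0.000798321	1.82487	0.0415148
2.8115457	2.744e-07	0.0394253	0.000947935	1.83123	0.0458967
3.0546331	2.13965e-07	0.0374708	0.00110938	1.83812	0.0507225
3.3187378	1.6684e-07	0.0355862	0.00128063	1.84544	0.0559822
3.6056772	1.30095e-07	0.033771	0.00146669	1.85314	0.0617874
3.9174255	1.01442e-07	0.0320249	0.00166883	1.86112	0.0681945
4.2561276	7.90998e-08	0.0303472	0.00188326	1.86935	0.0752703
4.6241141	6.16785e-08	0.0287372	0.00211442	1.87775	0.0830819
5.0239169	4.80941e-08	0.0271938	0.00236507	1.88628	0.0916865
5.4582867	3.75017e-08	0.0257161	0.00262913	1.89491	0.100863
5.9302123	2.92421e-08	0.0243029	0.00291601	1.90359	0.110958
6.4429408	2.28017e-08	0.0229527	0.00321872	1.91228	0.122261
7	1.77797e-08	0.0216642	0.00354607	1.92098	0.134751
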
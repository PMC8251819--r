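# medium: water
# density_g_cm3: 1
# composition: H=0.1119 O=0.8881
# columns: energy[MeV] mu_photo mu_compton mu_pair [cm^2/g] s_col s_rad [MeV cm^2/g]
energy_MeV	mu_photo	mu_compton	mu_pair	s_col	s_rad
0.01	4.74	0.214096	0	22.9352	3.9e-05
0.010864604	3.69604	0.213417	0	21.5007	4.38016e-05
0.011803962	2.88201	0.212687	0	20.1548	4.91943e-05
0.012824537	2.24726	0.2119	0	18.8926	5.5251e-05
0.013933352	1.75231	0.211054	0	17.7093	6.20534e-05
0.015138035	1.36637	0.210145	0	16.6005	6.96933e-05
0.016446875	1.06544	0.20917	0	15.5618	7.82738e-05
0.017868878	0.830781	0.208123	0	14.5893	8.79107e-05
0.019413829	0.647806	0.207001	0	13.679	9.8734e-05
0.021092356	0.50513	0.205801	0	12.8273	0.00011089
0.022916009	0.393878	0.204518	0	12.0307	0.000124542
0.024897337	0.307128	0.203148	0	11.286	0.000139876
0.02704997	0.239485	0.201687	0	10.5899	0.000157097
0.029388721	0.18674	0.200131	0	9.93961	0.000176438
0.031929682	0.145611	0.198477	0	9.33227	0.000198161
0.034690335	0.113541	0.196721	0	8.76529	0.000222558
0.037689675	0.0885342	0.194861	0	8.23618	0.000249959
0.040948339	0.069035	0.192893	0	7.74259	0.000280734
0.044488748	0.0538304	0.190815	0	7.28234	0.000315297
0.048335263	0.0419746	0.188626	0	6.85334	0.000354115
0.052514349	0.0327299	0.186325	0	6.45363	0.000397713
0.05705476	0.0255213	0.18391	0	6.0814	0.000446679
0.061987737	0.0199004	0.181383	0	5.7349	0.000501673
0.067347221	0.0155174	0.178744	0	5.41251	0.000563438
0.073170089	0.0120998	0.175995	0	5.11272	0.000632807
0.079496403	0.00943487	0.173139	0	4.8341	0.000710717
0.086369694	0.00735689	0.170181	0	4.57529	0.000798218
0.093837252	0.00573657	0.167124	0	4.33505	0.000896493
0.10195046	0.00447312	0.163974	0	4.1122	0.0010005
0.11076513	0.00348794	0.160737	0	3.90562	0.00109349
0.12034193	0.00271974	0.157421	0	3.7143	0.00119513
0.13074674	0.00212073	0.154034	0	3.53726	0.00130621
0.14205116	0.00165365	0.150584	0	3.3736	0.00142762
0.15433296	0.00128944	0.147079	0	3.22247	0.00156031
0.16767664	0.00100545	0.14353	0	3.08307	0.00170533
0.18217403	0.000784005	0.139945	0	2.95468	0.00186384
0.19792487	0.000611332	0.136334	0	2.8366	0.00203707
0.21503753	0.000476689	0.132707	0	2.72817	0.00222641
0.23362976	0.000371701	0.129072	0	2.6288	0.00243335
0.25382949	0.000289836	0.125438	0	2.53793	0.00265952
0.27577568	0.000226001	0.121814	0	2.45501	0.00290671
0.29961936	0.000176225	0.118206	0	2.37957	0.00317688
0.32552457	0.000137413	0.114622	0	2.31113	0.00347216
0.35366955	0.000107148	0.111068	0	2.24926	0.00379488
0.38424796	8.35495e-05	0.10755	0	2.19355	0.0041476
0.41747019	6.51481e-05	0.104072	0	2.14362	0.0045331
0.45356482	5.07996e-05	0.100637	0	2.09881	0.00495443
0.49278022	3.96113e-05	0.0972511	0	2.0576	0.00541493
0.53538619	3.08871e-05	0.0939153	0	2.02095	0.00597796
0.58167589	2.40844e-05	0.0906325	0	1.98855	0.00661364
0.63196782	1.87799e-05	0.0874048	0	1.96011	0.00731693
0.686608	1.46437e-05	0.0842338	0	1.93536	0.008095
0.7459724	1.14185e-05	0.0811209	0	1.91404	0.00895581
0.81046947	8.90366e-06	0.0780673	0	1.89589	0.00990815
0.88054298	6.94267e-06	0.0750743	0	1.88068	0.0109618
0.95667507	5.41359e-06	0.0721427	0	1.86819	0.0121274
1.0393896	4.22127e-06	0.0692735	7.62701e-07	1.85818	0.0134223
1.1292556	3.29156e-06	0.0664678	4.70419e-06	1.85046	0.0148622
1.2268915	2.56661e-06	0.0637263	8.98647e-06	1.84482	0.0164565
1.332969	2.00133e-06	0.0610501	3.15719e-05	1.84108	0.0182218
1.448218	1.56055e-06	0.05844	6.15367e-05	1.83906	0.0201765
1.5734315	1.21684e-06	0.0558969	0.000121262	1.83858	0.0223409
1.7094711	9.4884e-07	0.0534216	0.000206967	1.83949	0.0247374
1.8572726	7.39863e-07	0.051015	0.000300082	1.84165	0.0273911
2.0178531	5.76912e-07	0.0486776	0.00040214	1.8449	0.0303243
2.1923175	4.4985e-07	0.0464101	0.000520776	1.84912	0.033525
2.3818661	3.50773e-07	0.044213	0.000649669	1.85418	0.0370635
2.5878032	2.73517e-07	0.0420867	0.00078795	1.85998	0.0409755
2.8115457	2.13276e-07	0.0400312	0.00093562	1.86641	0.0453004
3.0546331	1.66303e-07	0.0380468	0.00109497	1.87338	0.0500635
3.3187378	1.29676e-07	0.0361331	0.00126399	1.88079	0.0552549
3.6056772	1.01116e-07	0.0342901	0.00144763	1.88858	0.0609847
3.9174255	7.88454e-08	0.0325171	0.00164715	1.89668	0.0673086
4.2561276	6.14801e-08	0.0308136	0.0018588	1.90501	0.0742925
4.6241141	4.79394e-08	0.0291788	0.00208695	1.91353	0.0820026
5.0239169	3.7381e-08	0.0276118	0.00233435	1.92218	0.0904954
5.4582867	2.9148e-08	0.0261114	0.00259497	1.93093	0.0995526
5.9302123	2.27283e-08	0.0246764	0.00287813	1.93973	0.109516
6.4429408	1.77225e-08	0.0233055	0.00317691	1.94855	0.120672
7	1.38192e-08	0.0219972	0.0035	1.95737	0.133
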
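# medium: air
# density_g_cm3: 0.0012048
# composition: C=0.000124 N=0.755267 O=0.231781 Ar=0.012828
# columns: energy[MeV] mu_photo mu_compton mu_pair [cm^2/g] s_col s_rad [MeV cm^2/g]
energy_MeV	mu_photo	mu_compton	mu_pair	s_col	s_rad
0.01	4.81526	0.192533	0	19.7529	3.85763e-05
0.010864604	3.75472	0.191923	0	18.5303	4.33258e-05
0.011803962	2.92777	0.191266	0	17.382	4.86599e-05
0.012824537	2.28294	0.190559	0	16.304	5.46508e-05
0.013933352	1.78014	0.189798	0	15.2925	6.13793e-05
0.015138035	1.38807	0.188981	0	14.3438	6.89362e-05
0.016446875	1.08235	0.188103	0	13.4543	7.74234e-05
0.017868878	0.843972	0.187162	0	12.6207	8.69556e-05
0.019413829	0.658091	0.186154	0	11.8398	9.76614e-05
0.021092356	0.51315	0.185074	0	11.1086	0.000109685
0.022916009	0.400132	0.18392	0	10.4242	0.000123189
0.024897337	0.312005	0.182688	0	9.78387	0.000138356
0.02704997	0.243287	0.181374	0	9.18498	0.00015539
0.029388721	0.189705	0.179975	0	8.62508	0.000174522
0.031929682	0.147923	0.178488	0	8.10184	0.000196008
0.034690335	0.115344	0.176909	0	7.61306	0.000220141
0.037689675	0.0899399	0.175236	0	7.15666	0.000247244
0.040948339	0.0701311	0.173466	0	6.73065	0.000277684
0.044488748	0.0546851	0.171598	0	6.3332	0.000311872
0.048335263	0.042641	0.169629	0	5.96253	0.000350268
0.052514349	0.0332496	0.167559	0	5.61701	0.000393393
0.05705476	0.0259265	0.165388	0	5.29507	0.000441826
0.061987737	0.0202163	0.163115	0	4.99525	0.000496223
0.067347221	0.0157638	0.160742	0	4.71618	0.000557317
0.073170089	0.0122919	0.15827	0	4.45655	0.000625932
0.079496403	0.00958467	0.155702	0	4.21516	0.000702996
0.086369694	0.0074737	0.153041	0	3.99085	0.000789547
0.093837252	0.00582766	0.150292	0	3.78257	0.000886754
0.10195046	0.00454415	0.147459	0	3.58929	0.000989632
0.11076513	0.00354332	0.144549	0	3.41008	0.00108161
0.12034193	0.00276292	0.141567	0	3.24405	0.00118215
0.13074674	0.0021544	0.138521	0	3.09038	0.00129202
0.14205116	0.00167991	0.135418	0	2.94828	0.00141211
0.15433296	0.00130992	0.132266	0	2.81705	0.00154336
0.16767664	0.00102141	0.129074	0	2.69598	0.00168681
0.18217403	0.000796453	0.125851	0	2.58445	0.00184359
0.19792487	0.000621039	0.122603	0	2.48187	0.00201494
0.21503753	0.000484258	0.119341	0	2.38768	0.00220223
0.23362976	0.000377603	0.116073	0	2.30135	0.00240691
0.25382949	0.000294438	0.112805	0	2.22241	0.00263063
0.27577568	0.000229589	0.109545	0	2.15039	0.00287513
0.29961936	0.000179024	0.106301	0	2.08487	0.00314237
0.32552457	0.000139595	0.103078	0	2.02545	0.00343444
0.35366955	0.00010885	0.0998823	0	1.97175	0.00375365
0.38424796	8.4876e-05	0.0967181	0	1.92343	0.00410254
0.41747019	6.61825e-05	0.0935901	0	1.88015	0.00448385
0.45356482	5.16062e-05	0.0905019	0	1.8416	0.00490061
0.49278022	4.02402e-05	0.0874566	0	1.80748	0.0053561
0.53538619	3.13775e-05	0.0844568	0	1.77752	0.00591302
0.58167589	2.44668e-05	0.0815046	0	1.75146	0.0065418
0.63196782	1.90781e-05	0.078602	0	1.72905	0.00723744
0.686608	1.48762e-05	0.0757503	0	1.71005	0.00800706
0.7459724	1.15998e-05	0.0729509	0	1.69424	0.00885852
0.81046947	9.04502e-06	0.0702049	0	1.68141	0.00980052
0.88054298	7.05291e-06	0.0675133	0	1.67135	0.0108427
0.95667507	5.49954e-06	0.0648769	0	1.66388	0.0119957
1.0393896	4.2883e-06	0.0622967	7.54415e-07	1.65881	0.0132765
1.1292556	3.34382e-06	0.0597736	4.65309e-06	1.65596	0.0147007
1.2268915	2.60736e-06	0.0573082	8.88884e-06	1.65517	0.0162777
1.332969	2.0331e-06	0.0549015	3.1229e-05	1.65628	0.0180238
1.448218	1.58532e-06	0.0525543	6.08682e-05	1.65915	0.0199573
1.5734315	1.23616e-06	0.0502673	0.000119945	1.66363	0.0220982
1.7094711	9.63906e-07	0.0480413	0.000204718	1.66958	0.0244687
1.8572726	7.5161e-07	0.0458771	0.000296822	1.67689	0.0270935
2.0178531	5.86072e-07	0.0437751	0.000397771	1.68543	0.0299949
2.1923175	4.56993e-07	0.041736	0.000515118	1.69509	0.0331608
2.3818661	3.56343e-07	0.0397602	0.000642611	1.70577	0.0366609
2.5878032	2.7786e-07	0.037848	0.00077939	1.71738	0.0405304
2.8115457	2.16663e-07	0.0359995	0.000925456	1.72981	0.0448083
3.0546331	1.68944e-07	0.0342149	0.00108307	1.743	0.0495197
3.3187378	1.31735e-07	0.032494	0.00125026	1.75686	0.0546547
3.6056772	1.02721e-07	0.0308366	0.00143191	1.77132	0.0603222
3.9174255	8.00972e-08	0.0292422	0.00162926	1.78633	0.0665774
4.2561276	6.24562e-08	0.0277103	0.00183861	1.80181	0.0734854
4.6241141	4.87006e-08	0.0262401	0.00206428	1.81773	0.0811117
5.0239169	3.79745e-08	0.0248309	0.00230899	1.83403	0.0895123
5.4582867	2.96108e-08	0.0234816	0.00256678	1.85066	0.0984711
5.9302123	2.30892e-08	0.0221912	0.00284686	1.86759	0.108326
6.4429408	1.80039e-08	0.0209583	0.00314239	1.88479	0.119361
7	1.40387e-08	0.0197818	0.00346198	1.90222	0.131555
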
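# medium: bone_cortical
# density_g_cm3: 1.92
# composition: H=0.034 C=0.155 N=0.042 O=0.435 Na=0.001 Mg=0.002 P=0.103 S=0.003 Ca=0.225
# columns: energy[MeV] mu_photo mu_compton mu_pair [cm^2/g] s_col s_rad [MeV cm^2/g]
energy_MeV	mu_photo	mu_compton	mu_pair	s_col	s_rad
0.01	37.4119	0.198551	0	19.636	5.48663e-05
0.010864604	29.1721	0.197922	0	18.4319	6.16214e-05
0.011803962	22.7471	0.197244	0	17.3	6.9208e-05
0.012824537	17.7372	0.196515	0	16.2364	7.77288e-05
0.013933352	13.8307	0.195731	0	15.2376	8.72986e-05
0.015138035	10.7845	0.194888	0	14.2999	9.80466e-05
0.016446875	8.4093	0.193983	0	13.4201	0.000110118
0.017868878	6.55719	0.193012	0	12.5949	0.000123675
0.019413829	5.11301	0.191972	0	11.8214	0.000138902
0.021092356	3.98689	0.190859	0	11.0966	0.000156003
0.022916009	3.1088	0.189669	0	10.4177	0.00017521
0.024897337	2.4241	0.188398	0	9.78208	0.000196781
0.02704997	1.89021	0.187043	0	9.18726	0.000221009
0.029388721	1.4739	0.1856	0	8.63083	0.000248219
0.031929682	1.14928	0.184066	0	8.11053	0.000278779
0.034690335	0.896158	0.182438	0	7.62424	0.000313101
0.037689675	0.698784	0.180713	0	7.16991	0.00035165
0.040948339	0.54488	0.178888	0	6.74563	0.000394944
0.044488748	0.424873	0.176961	0	6.34959	0.000443569
0.048335263	0.331297	0.174931	0	5.98007	0.00049818
0.052514349	0.258331	0.172796	0	5.63547	0.000559515
0.05705476	0.201435	0.170557	0	5.31425	0.000628401
0.061987737	0.15707	0.168213	0	5.01498	0.000705768
0.067347221	0.122476	0.165766	0	4.7363	0.000792661
0.073170089	0.0955013	0.163217	0	4.47696	0.000890251
0.079496403	0.0744676	0.160569	0	4.23574	0.000999857
0.086369694	0.0580665	0.157825	0	4.01153	0.00112296
0.093837252	0.0452777	0.15499	0	3.80326	0.00126121
0.10195046	0.0353055	0.152068	0	3.60994	0.00140753
0.11076513	0.0275296	0.149067	0	3.43065	0.00153836
0.12034193	0.0214664	0.145992	0	3.2645	0.00168134
0.13074674	0.0167385	0.14285	0	3.11069	0.00183762
0.14205116	0.013052	0.13965	0	2.96843	0.00200842
0.15433296	0.0101773	0.1364	0	2.83702	0.00219509
0.16767664	0.00793583	0.133109	0	2.71578	0.00239911
0.18217403	0.006188	0.129784	0	2.60409	0.0026221
0.19792487	0.00482513	0.126435	0	2.50134	0.00286582
0.21503753	0.00376242	0.123071	0	2.40699	0.00313218
0.23362976	0.00293377	0.119701	0	2.32052	0.00342331
0.25382949	0.00228762	0.116331	0	2.24144	0.00374149
0.27577568	0.00178378	0.112969	0	2.16932	0.00408924
0.29961936	0.00139091	0.109624	0	2.10371	0.00446932
0.32552457	0.00108457	0.1063	0	2.04422	0.00488473
0.35366955	0.000845701	0.103004	0	1.99048	0.00533874
0.38424796	0.00065944	0.0997411	0	1.94214	0.00583496
0.41747019	0.000514202	0.0965154	0	1.89887	0.0063773
0.45356482	0.000400951	0.0933306	0	1.86023	0.00697004
0.49278022	0.000312644	0.0901901	0	1.82538	0.00761788
0.53538619	0.000243786	0.0870965	0	1.79447	0.00840997
0.58167589	0.000190093	0.0840521	0	1.76724	0.00930427
0.63196782	0.000148226	0.0810587	0	1.74344	0.0102937
0.686608	0.00011558	0.0781179	0	1.72285	0.0113883
0.7459724	9.01242e-05	0.075231	0	1.70524	0.0125993
0.81046947	7.02749e-05	0.0723992	0	1.69039	0.0139391
0.88054298	5.47972e-05	0.0696234	0	1.67811	0.0154213
0.95667507	4.27284e-05	0.0669047	0	1.66818	0.0170612
1.0393896	3.33177e-05	0.0642439	1.07299e-06	1.66043	0.0188829
1.1292556	2.59796e-05	0.0616418	6.618e-06	1.65468	0.0209085
1.2268915	2.02578e-05	0.0590994	1.26424e-05	1.65074	0.0231514
1.332969	1.57961e-05	0.0566175	4.44163e-05	1.64846	0.025635
1.448218	1.23171e-05	0.0541969	8.65716e-05	1.64768	0.0283849
1.5734315	9.60431e-06	0.0518385	0.000170595	1.64825	0.0314298
1.7094711	7.48901e-06	0.0495429	0.000291167	1.65003	0.0348014
1.8572726	5.8396e-06	0.047311	0.000422164	1.65289	0.0385346
2.0178531	4.55346e-06	0.0451433	0.000565742	1.6567	0.0426612
2.1923175	3.55058e-06	0.0430405	0.000732643	1.66134	0.047164
2.3818661	2.76858e-06	0.0410029	0.000913973	1.66672	0.0521421
2.5878032	2.15882e-06	0.0390309	0.00110851	1.67273	0.0576456
2.8115457	1.68335e-06	0.0371247	0.00131626	1.67928	0.06373
3.0546331	1.3126e-06	0.0352843	0.00154043	1.68628	0.0704308
3.3187378	1.02351e-06	0.0335097	0.00177822	1.69366	0.0777343
3.6056772	7.98085e-07	0.0318004	0.00203657	1.70135	0.085795
3.9174255	6.22311e-07	0.0301562	0.00231726	1.70928	0.0946917
4.2561276	4.8525e-07	0.0285764	0.00261501	1.71741	0.104517
4.6241141	3.78377e-07	0.0270603	0.00293598	1.72568	0.115364
5.0239169	2.95041e-07	0.025607	0.00328403	1.73404	0.127312
5.4582867	2.3006e-07	0.0242156	0.00365068	1.74247	0.140053
5.9302123	1.7939e-07	0.0228848	0.00404903	1.75092	0.154071
6.4429408	1.39881e-07	0.0216134	0.00446936	1.75937	0.169765
7	1.09073e-07	0.0204001	0.0049239	1.76779	0.187108
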
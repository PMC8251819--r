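# medium: lung
# density_g_cm3: 0.26
# composition: H=0.103 C=0.105 N=0.031 O=0.749 Na=0.002 P=0.002 S=0.003 Cl=0.003 K=0.002
# columns: energy[MeV] mu_photo mu_compton mu_pair [cm^2/g] s_col s_rad [MeV cm^2/g]
energy_MeV	mu_photo	mu_compton	mu_pair	s_col	s_rad
0.01	5.03987	0.212319	0	22.7163	3.84936e-05
0.010864604	3.92987	0.211646	0	21.2959	4.32328e-05
0.011803962	3.06433	0.210922	0	19.9632	4.85556e-05
0.012824537	2.38943	0.210142	0	18.7134	5.45336e-05
0.013933352	1.86317	0.209303	0	17.5416	6.12477e-05
0.015138035	1.45282	0.208402	0	16.4436	6.87883e-05
0.016446875	1.13284	0.207434	0	15.415	7.72574e-05
0.017868878	0.883339	0.206396	0	14.4519	8.67691e-05
0.019413829	0.688788	0.205284	0	13.5504	9.7452e-05
0.021092356	0.537086	0.204093	0	12.7069	0.00010945
0.022916009	0.418796	0.202821	0	11.918	0.000122925
0.024897337	0.326558	0.201462	0	11.1804	0.00013806
0.02704997	0.254636	0.200013	0	10.491	0.000155057
0.029388721	0.198553	0.19847	0	9.84686	0.000174147
0.031929682	0.154823	0.19683	0	9.24532	0.000195588
0.034690335	0.120724	0.195089	0	8.68373	0.000219668
0.037689675	0.0941353	0.193244	0	8.15965	0.000246713
0.040948339	0.0734025	0.191292	0	7.67074	0.000277088
0.044488748	0.0572359	0.189232	0	7.21485	0.000311203
0.048335263	0.04463	0.187061	0	6.7899	0.000349517
0.052514349	0.0348005	0.184778	0	6.39397	0.000392549
0.05705476	0.0271359	0.182384	0	6.02524	0.000440879
0.061987737	0.0211593	0.179877	0	5.682	0.000495159
0.067347221	0.0164991	0.17726	0	5.36265	0.000556121
0.073170089	0.0128653	0.174534	0	5.06567	0.00062459
0.079496403	0.0100318	0.171703	0	4.78966	0.000701488
0.086369694	0.00782232	0.168769	0	4.53328	0.000787854
0.093837252	0.00609949	0.165737	0	4.29528	0.000884852
0.10195046	0.00475611	0.162613	0	4.07451	0.000987509
0.11076513	0.0037086	0.159403	0	3.86987	0.00107929
0.12034193	0.0028918	0.156115	0	3.68033	0.00117961
0.13074674	0.0022549	0.152756	0	3.50494	0.00128925
0.14205116	0.00175827	0.149334	0	3.3428	0.00140908
0.15433296	0.00137102	0.145859	0	3.19308	0.00154005
0.16767664	0.00106906	0.142339	0	3.05498	0.00168319
0.18217403	0.000833604	0.138784	0	2.92778	0.00183964
0.19792487	0.000650007	0.135203	0	2.8108	0.00201062
0.21503753	0.000506847	0.131606	0	2.70338	0.0021975
0.23362976	0.000395216	0.128001	0	2.60494	0.00240175
0.25382949	0.000308172	0.124397	0	2.5149	0.00262498
0.27577568	0.000240299	0.120803	0	2.43276	0.00286897
0.29961936	0.000187374	0.117225	0	2.35802	0.00313563
0.32552457	0.000146106	0.113671	0	2.29022	0.00342707
0.35366955	0.000113927	0.110147	0	2.22892	0.0037456
0.38424796	8.88351e-05	0.106657	0	2.17374	0.00409374
0.41747019	6.92697e-05	0.103208	0	2.12428	0.00447424
0.45356482	5.40134e-05	0.0998023	0	2.08019	0.0048901
0.49278022	4.21172e-05	0.0964441	0	2.04113	0.00534461
0.53538619	3.28411e-05	0.093136	0	2.00679	0.00590033
0.58167589	2.5608e-05	0.0898805	0	1.97688	0.00652777
0.63196782	1.9968e-05	0.0866795	0	1.95109	0.00722192
0.686608	1.55702e-05	0.0835348	0	1.92917	0.00798989
0.7459724	1.21409e-05	0.0804477	0	1.91087	0.00883952
0.81046947	9.46694e-06	0.0774195	0	1.89593	0.0097795
0.88054298	7.38189e-06	0.0744513	0	1.88413	0.0108194
0.95667507	5.75607e-06	0.071544	0	1.87526	0.01197
1.0393896	4.48833e-06	0.0686987	7.52797e-07	1.86909	0.013248
1.1292556	3.4998e-06	0.0659162	4.64311e-06	1.86544	0.0146692
1.2268915	2.72898e-06	0.0631975	8.86978e-06	1.86411	0.0162428
1.332969	2.12794e-06	0.0605435	3.1162e-05	1.86492	0.0179852
1.448218	1.65927e-06	0.057955	6.07376e-05	1.86736	0.0199145
1.5734315	1.29383e-06	0.055433	0.000119687	1.87116	0.0220508
1.7094711	1.00887e-06	0.0529783	0.000204279	1.87619	0.0244162
1.8572726	7.8667e-07	0.0505916	0.000296185	1.88229	0.0270354
2.0178531	6.1341e-07	0.0482737	0.000396918	1.88933	0.0299306
2.1923175	4.7831e-07	0.046025	0.000514014	1.89718	0.0330897
2.3818661	3.72964e-07	0.0438461	0.000641233	1.90574	0.0365823
2.5878032	2.90821e-07	0.0417374	0.000777719	1.91488	0.0404435
2.8115457	2.26769e-07	0.039699	0.000923471	1.92451	0.0447122
3.0546331	1.76824e-07	0.037731	0.00108075	1.93454	0.0494135
3.3187378	1.3788e-07	0.0358333	0.00124758	1.94487	0.0545375
3.6056772	1.07512e-07	0.0340055	0.00142884	1.95544	0.0601928
3.9174255	8.38334e-08	0.0322473	0.00162576	1.96618	0.0664346
4.2561276	6.53696e-08	0.0305579	0.00183466	1.97701	0.0733278
4.6241141	5.09723e-08	0.0289367	0.00205985	1.98789	0.0809378
5.0239169	3.97459e-08	0.0273827	0.00230404	1.99877	0.0893203
5.4582867	3.09921e-08	0.0258947	0.00256128	2.00961	0.0982599
5.9302123	2.41662e-08	0.0244716	0.00284075	2.02037	0.108094
6.4429408	1.88437e-08	0.0231121	0.00313565	2.03103	0.119105
7	1.46935e-08	0.0218146	0.00345455	2.04154	0.131273
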
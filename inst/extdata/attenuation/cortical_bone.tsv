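energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	2512.43	175.057	175.056	0.205431	2337.17
    1.5	955.266	174.847	174.846	0.205033	780.215
      2	522.142	174.637	174.636	0.204636	347.301
    2.5	281.674	100.205	100.204	0.204242	181.266
      3	170.785	64.5044	64.5032	0.203849	106.078
      4	78.4029	34.3365	34.3349	0.20307	43.8649
 4.0381	76.5787	 33.797	33.7954	0.203038	42.5453
 4.0381	280.879	236.029	236.027	0.203038	44.6132
      5	157.473	 119.54	 134.45	0.202298	22.8205
      6	97.0366	77.1006	84.6499	0.201535	12.1852
      8	44.9934	 38.553	41.0511	0.200029	3.74232
     10	28.5019	26.2879	27.5148	0.198553	0.788527
     12	17.1383	15.7364	16.3481	0.197106	0.593049
     15	 9.2071	8.37295	 8.6311	0.194986	0.381007
     18	 5.7133	5.10409	5.23313	0.192925	0.287239
     20	4.34032	3.83014	3.91519	0.191583	0.233545
     25	2.37211	1.99071	 2.0207	0.188335	0.163074
     28	1.75192	1.42277	 1.4381	0.186456	0.127369
     30	1.45897	1.15788	1.16681	0.18523	0.106932
     32	1.25335	0.967851	0.972274	0.184027	0.0970475
     35	1.01793	0.753088	0.752588	0.18226	0.0830853
     40	0.751803	0.515458	0.509654	0.179416	0.0627327
     45	0.582275	0.364789	0.355578	0.17669	0.0500075
     50	0.467995	0.265878	0.254315	0.174074	0.0396054
     55	0.396611	0.205271	0.192009	0.171562	0.0330394
     60	0.343338	0.161252	0.146619	0.169149	0.0275704
     65	0.306341	0.131707	0.115937	0.166827	0.0235768
     70	0.276941	0.108895	0.092138	0.164593	0.0202101
     75	0.253129	0.090982	0.0733486	0.16244	0.01734
     80	0.233524	0.0767097	0.0582877	0.160365	0.0148716
     90	0.209363	0.0609398	0.0411659	0.15643	0.0117668
    100	0.190812	0.0497026	0.0287663	0.152758	0.00928727
    110	0.179559	0.0443535	0.0224151	0.149322	0.00782115
    120	0.170053	0.0402041	0.0173801	 0.1461	0.00657325
    130	0.161895	0.0369409	0.0133301	0.143071	0.00549421
    150	0.148557	0.0322631	0.0073221	0.137523	0.00371202
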
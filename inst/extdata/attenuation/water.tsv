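energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	4077.21	  4.944	4.94357	0.221513	4072.05
    1.5	1375.92	  4.944	4.94336	0.221083	1370.75
      2	617.263	  4.944	4.94314	0.220656	  612.1
    2.5	325.411	  4.944	4.94293	0.22023	320.248
      3	192.871	  4.944	4.94273	0.219807	187.708
      4	82.7779	  4.944	4.94231	0.218967	77.6167
      5	42.9158	  4.944	4.94191	0.218135	37.7557
      6	24.6458	  4.944	4.94151	0.217312	19.4869
      8	10.3725	  4.944	4.94074	0.215689	5.21604
     10	5.32913	  4.944	4.93998	0.214097	0.175051
     12	3.15758	2.77953	2.77479	0.212536	0.170256
     15	1.67268	  1.374	 1.3682	0.21025	0.0942279
     18	1.05372	0.769189	0.762386	0.208028	0.0833044
     20	0.809645	0.550301	0.542854	0.206581	0.06021
     25	0.527669	0.274126	0.265151	0.203079	0.0594392
     28	0.426614	0.19275	0.182911	0.201052	0.0426506
     30	0.375561	 0.1557	0.145307	0.199731	0.0305239
     32	0.347891	0.129663	0.118731	0.198433	0.0307268
     35	0.313127	0.100731	0.0890194	0.196528	0.0275792
     40	0.268268	0.0694726	0.0565343	0.193461	0.0182728
     45	0.245477	0.053263	0.0391816	0.190522	0.0157739
     50	0.226885	0.04223	0.027082	0.187701	0.0121015
     55	0.215615	0.0364027	0.0202585	0.184993	0.0103638
     60	0.205839	0.0319021	0.0148262	0.18239	0.00862263
     65	0.199413	0.0300731	0.0121251	0.179887	0.007401
     70	0.193633	0.0285075	0.0097423	0.177478	0.00641319
     75	0.188391	0.0271528	0.0076209	0.175156	0.00561343
     80	0.183611	0.02597	0.00571817	0.172919	0.00497369
     90	0.176692	0.0256971	0.00413213	0.168676	0.00388385
    100	0.170687	0.0254624	0.00273352	0.164717	0.00323677
    110	0.165777	0.0259771	0.00221312	0.161012	0.00255231
    120	0.161389	0.0264467	0.00175933	0.157537	0.00209187
    130	0.157428	0.0268773	0.00136407	0.154271	0.0017924
    150	0.150534	0.0276412	0.000721901	0.148289	0.00152345
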
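energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	   4590	5.56566	5.56527	0.199543	4584.24
    1.5	   1549	5.56566	5.56508	0.199156	1543.24
      2	  694.9	5.56566	5.56489	0.19877	689.136
    2.5	366.316	5.56566	 5.5647	0.198387	360.553
      3	  217.1	5.56566	5.56451	0.198006	211.337
      4	  93.15	5.56566	5.56414	0.197249	87.3886
      5	  48.27	5.56566	5.56378	 0.1965	42.5097
      6	   27.7	5.56566	5.56342	0.195758	21.9408
      8	  11.63	5.56566	5.56272	0.194296	5.87298
     10	  5.952	5.56566	5.56204	0.192862	0.197096
     12	3.50736	3.12848	 3.1242	0.191456	0.191707
     15	  1.836	1.54573	 1.5405	0.189397	 0.1061
     18	1.13961	0.864541	0.858413	0.187395	0.0938001
     20	 0.8651	0.617958	0.611249	0.186092	0.067759
     25	0.548422	0.306642	0.298557	0.182937	0.066928
     28	0.435092	0.214819	0.205956	0.181111	0.0480242
     30	 0.3779	0.172973	0.163611	0.179921	0.0343682
     32	0.34704	0.143538	0.13369	0.178752	0.0345981
     35	0.308325	0.110785	0.100235	0.177036	0.0310539
     40	 0.2585	0.0753122	0.0636572	0.174273	0.0205697
     45	0.233504	0.0568029	0.0441181	0.171625	0.0177612
     50	 0.2132	0.0441363	0.0304907	0.169084	0.013625
     55	0.201125	0.0373539	0.0228109	0.166645	0.0116696
     60	 0.1907	0.0320764	0.0166942	 0.1643	0.00970552
     65	0.184032	0.0298206	0.0136528	0.162045	0.00833346
     70	0.178066	0.0278738	0.0109697	0.159875	0.0072212
     75	0.172686	0.0261758	0.00858106	0.157784	0.00632067
     80	 0.1678	0.0246811	0.00643792	0.155768	0.005594
     90	0.160972	0.0240788	0.00465275	0.151946	0.00437318
    100	 0.1551	0.0235525	0.00307791	0.148379	0.00364271
    110	0.150408	0.023899	0.00249195	0.145042	0.00287388
    120	0.146249	0.0242198	0.00198099	0.141912	0.00235543
    130	0.142524	0.0245186	0.00153593	0.13897	0.00201823
    150	 0.1361	0.0250622	0.000812854	0.133581	0.001706
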
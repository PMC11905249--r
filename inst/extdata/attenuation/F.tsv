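energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	7.93562	7.69194	7.69158	0.189049	0.0549966
    1.5	7.96254	7.69191	7.69136	0.188682	0.0824926
      2	7.98945	7.69188	7.69115	0.188317	0.109987
    2.5	8.01637	7.69185	7.69094	0.187954	0.13748
      3	8.04329	7.69182	7.69073	0.187593	0.164972
      4	8.09714	7.69175	7.69031	0.186876	0.21995
      5	  8.151	7.69169	7.68991	0.186166	0.274923
      6	8.20486	7.69163	7.68951	0.185463	0.329891
      8	8.31261	7.69151	7.68872	0.184078	0.43981
     10	8.42039	 7.6914	7.68797	0.182719	0.549708
     12	4.90085	4.35057	4.34652	0.181387	0.372944
     15	2.57202	2.16578	2.16083	0.179436	0.231757
     18	1.54453	1.21692	1.21111	0.17754	0.155875
     20	1.16567	0.871941	0.865585	0.176305	0.123783
     25	0.674132	0.432529	0.424869	0.173316	0.0759478
     28	0.524753	0.302652	0.294255	0.171586	0.0589119
     30	0.455278	0.243384	0.234514	0.170459	0.050305
     32	0.404773	0.200916	0.191586	0.169351	0.0438363
     35	0.347529	0.153808	0.143813	0.167725	0.0359905
     40	0.283351	0.102988	0.0919459	0.165108	0.0262974
     45	0.246711	0.0756539	0.0636362	0.162599	0.0204756
     50	 0.2203	0.0572061	0.0442782	0.160192	0.01583
     55	0.20392	0.0468226	0.0330445	0.157881	0.0129952
     60	0.19044	0.0389122	0.024339	0.15566	0.0104418
     65	0.182436	0.0350564	0.0197388	0.153523	0.00917393
     70	0.175195	0.0318286	0.0158136	0.151467	0.00791495
     75	0.168562	0.0290866	0.0124173	0.149486	0.00665899
     80	0.162415	0.0267231	0.00943934	0.147576	0.00539948
     90	0.155107	0.0251901	0.00678566	0.143955	0.00436672
    100	0.148344	0.0239269	0.00452914	0.140576	0.00323844
    110	0.143969	0.0239501	0.00366891	0.137414	0.0028857
    120	0.139875	0.0239896	0.00292038	0.134449	0.00250577
    130	0.136037	0.024042	0.00226794	0.131661	0.00210812
    150	0.129047	0.0241759	0.0012018	0.126556	0.00128898
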
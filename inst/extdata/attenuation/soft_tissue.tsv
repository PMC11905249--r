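energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	3569.25	 6.8414	6.84097	0.219468	3562.19
    1.5	1199.66	6.83916	6.83852	0.219043	 1192.6
      2	538.051	6.83692	6.83607	0.218619	530.996
    2.5	283.469	5.99565	 5.9946	0.218197	277.256
      3	168.007	5.54017	5.53891	0.217778	 162.25
      4	72.2823	 5.0985	5.09683	0.216946	66.9685
      5	39.1553	6.39606	6.39399	0.216122	32.5452
      6	22.8261	5.80328	5.80081	0.215306	  16.81
      8	9.93363	5.20409	5.20085	0.213698	4.51908
     10	5.37971	4.98476	4.98078	0.212121	0.186817
     12	3.19966	2.81867	2.81397	0.210574	0.17512
     15	1.70415	1.40352	1.39778	0.208309	0.098065
     18	1.07692	0.79309	0.78635	0.206108	0.0844613
     20	0.829539	0.570534	0.563156	0.204674	0.0617093
     25	0.536328	0.286035	0.277143	0.201204	0.0579813
     28	0.433116	0.201682	0.191934	0.199196	0.0419858
     30	0.381363	0.16315	0.152852	0.197887	0.0306238
     32	0.352124	0.136097	0.125266	0.196601	0.0302571
     35	0.31598	0.105947	0.0943436	0.194714	0.0269225
     40	0.270252	0.0732297	0.0604108	0.191675	0.0181661
     45	0.246156	0.0558825	0.041931	0.188763	0.0154624
     50	0.227039	0.0441279	0.0291197	0.185968	0.011951
     55	0.215267	0.0378067	0.0218115	0.183285	0.0101699
     60	0.205239	0.0329829	0.0160647	0.180707	0.00846782
     65	0.198544	0.0308427	0.0130604	0.178227	0.0072569
     70	0.192592	0.0290662	0.0104742	0.175839	0.00627828
     75	0.187243	0.0275696	0.00821797	0.17354	0.0054854
     80	 0.1824	0.0262931	0.00622825	0.171323	0.0048492
     90	0.175391	0.0258443	0.00447839	0.167119	0.00379325
    100	0.169333	0.0255116	0.00299247	0.163196	0.00314425
    110	0.164419	0.0259453	0.00240065	0.159526	0.00249292
    120	0.160027	0.0263558	0.00189639	0.156083	0.00204751
    130	0.156063	0.0267439	0.00146619	0.152847	0.0017498
    150	0.149163	0.0274572	0.000786421	0.14692	0.00145642
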
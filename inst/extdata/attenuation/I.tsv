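energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	    900	899.192	899.192	0.166663	0.641401
    1.5	    900	898.872	898.872	0.16634	0.961759
      2	    900	898.553	898.552	0.166018	1.28189
    2.5	    900	898.233	898.233	0.165698	1.60179
      3	    900	897.914	897.913	0.16538	1.92147
      4	    900	897.276	897.275	0.164747	2.56013
      5	    900	 896.64	896.638	0.164122	 3.1979
      6	    620	617.197	617.195	0.163502	 2.6415
      8	    300	298.139	298.136	0.162281	 1.7013
     10	    162	160.696	160.693	0.161083	1.14623
     12	99.8308	98.8286	 98.825	0.159909	0.845912
     15	   55.2	54.4635	54.4591	0.158189	0.582692
     18	33.8022	33.2242	33.2191	0.156517	0.426518
     20	  25.46	24.9543	24.9486	0.155429	0.355921
     25	   14.1	13.7096	13.7028	0.152793	0.244359
     28	10.3401	9.99672	9.98932	0.151268	0.199513
     30	  8.561	8.24233	8.23451	0.150274	0.176212
     32	7.20985	6.91121	6.90299	0.149298	0.157567
33.1694	  6.553	 6.2647	6.25624	0.148735	0.148023
33.1694	  36.32	35.3437	35.3352	0.148735	0.836031
     35	31.6216	8.52521	30.7071	0.147865	0.766628
     40	  22.41	7.96872	21.6468	0.145557	0.617634
     45	16.3416	6.88372	15.6945	0.143345	0.503774
     50	  12.32	5.82217	11.7594	0.141223	0.419403
     55	9.55673	4.90679	9.06202	0.139186	0.355521
     60	  7.579	4.14087	7.13635	0.137228	0.305425
     65	6.11783	3.50613	 5.7174	0.135344	0.265087
     70	 5.0174	2.98497	4.65161	0.133531	0.232262
     75	4.17162	2.55617	3.83469	0.131785	0.205149
     80	   3.51	2.20176	3.19744	0.130101	0.182461
     90	2.56816	1.66553	2.29399	0.126909	0.147269
    100	  1.942	1.28489	1.69702	0.12393	0.12105
    110	1.52672	1.02151	1.30331	0.121143	0.102263
    120	1.22565	0.823449	1.01983	0.118529	0.0872942
    130	1.00142	0.671774	0.810214	0.116071	0.0751312
    150	 0.6978	0.460526	0.529568	0.11157	0.0566618
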
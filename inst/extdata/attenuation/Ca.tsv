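energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	    730	727.958	727.958	0.199142	1.84333
    1.5	    730	 727.04	 727.04	0.198756	2.76151
      2	    730	726.125	726.124	0.198371	3.67737
    2.5	404.766	402.024	402.023	0.197989	  2.545
      3	    250	 247.92	247.919	0.197608	1.88334
      4	 120.86	119.455	119.454	0.196853	1.20992
 4.0381	    118	116.612	116.611	0.196824	1.19237
 4.0381	   1026	1015.42	1015.42	0.196824	10.3829
      5	    558	484.552	 550.83	0.196105	6.97404
      6	    340	301.158	334.719	0.195365	5.08544
      8	    151	136.699	147.812	0.193906	 2.9943
     10	  93.41	85.4492	90.9154	0.192475	2.30215
     12	56.4698	 51.885	54.6191	0.191072	1.65967
     15	   30.5	28.0358	29.2018	0.189016	1.10917
     18	19.0054	17.4026	17.9981	0.187019	0.820343
     20	  14.46	13.1842	13.5862	0.185718	0.688059
     25	7.70618	6.91347	7.07568	0.182569	0.447925
     28	5.59786	4.95862	5.05846	0.180747	0.358652
     30	  4.608	4.04259	4.11578	0.17956	0.312659
     32	3.89974	3.38751	3.44241	0.178393	0.278939
     35	3.09315	2.64351	2.67903	0.17668	0.237434
     40	   2.19	1.81475	1.83065	0.173923	0.185423
     45	1.59629	 1.2748	1.27925	0.17128	0.145768
     50	  1.203	0.920596	0.918025	0.168745	0.116231
     55	0.957888	0.701725	0.694811	0.16631	0.0967668
     60	  0.778	0.54305	0.533044	0.16397	0.0809861
     65	0.651434	0.432746	0.420503	0.16172	0.0692116
     70	0.552687	0.347941	0.333941	0.159554	0.0591922
     75	0.474258	0.281654	0.26623	0.157467	0.050561
     80	  0.411	0.229106	0.212498	0.155455	0.0430469
     90	0.33563	0.168226	0.14984	0.151641	0.0341482
    100	   0.28	0.125064	0.105264	0.148081	0.0266548
    110	0.24901	0.102464	0.0815457	0.144751	0.0227138
    120	0.223724	0.0848427	0.0629643	0.141627	0.0191325
    130	0.202737	0.0708978	0.0481843	0.138691	0.0158615
    150	   0.17	0.0506822	0.0265882	0.133313	0.010099
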
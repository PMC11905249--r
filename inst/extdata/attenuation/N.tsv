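energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	3.71953	3.48593	3.48554	0.19943	0.0345524
    1.5	3.73629	  3.486	3.48542	0.199044	0.0518269
      2	3.75306	3.48607	 3.4853	0.198659	0.0691001
    2.5	3.76983	3.48614	3.48518	0.198276	0.0863722
      3	 3.7866	3.48621	3.48507	0.197895	0.103643
      4	3.82015	3.48635	3.48484	0.197138	0.138182
      5	3.85371	3.48649	3.48461	0.196389	0.172716
      6	3.88728	3.48662	3.48438	0.195648	0.207246
      8	3.95442	3.48688	3.48394	0.194187	0.276293
     10	 4.0216	3.48714	3.48352	0.192754	0.345324
     12	 2.3808	1.96097	1.95669	0.191348	0.232762
     15	1.29758	0.970041	0.964821	0.18929	0.143465
     18	0.820847	0.543751	0.537626	0.18729	0.0959315
     20	0.644714	0.389531	0.382827	0.185987	0.0758998
     25	0.416161	0.195068	0.186987	0.182834	0.0463404
     28	0.345804	0.137849	0.128991	0.181009	0.0358035
     30	0.312763	0.111827	0.10247	0.17982	0.0304737
     32	0.288943	0.0935728	0.0837305	0.178651	0.0265609
     35	0.261495	0.0733215	0.0627775	0.176936	0.0217811
     40	0.229853	0.0515171	0.0398686	0.174175	0.0158088
     45	0.211486	0.040309	0.0276313	0.171528	0.012326
     50	0.197551	0.0327343	0.0190964	0.168989	0.00946519
     55	0.188627	0.0288213	0.0142865	0.166551	0.00778928
     60	0.180882	0.0258292	0.0104556	0.164208	0.00621883
     65	0.176015	0.0247095	0.00855078	0.161954	0.00550969
     70	0.171423	0.0237649	0.00687037	0.159785	0.00476746
     75	0.167065	0.0229591	0.00537434	0.157695	0.00399572
     80	0.16291	0.022265	0.00403208	0.155681	0.00319763
     90	0.157375	0.0223292	0.00291403	0.151861	0.00259983
    100	0.152135	0.0223908	0.0019277	0.148296	0.00191095
    110	0.148223	0.0229557	0.00156071	0.144961	0.00170186
    120	0.144549	0.023467	0.0012407	0.141832	0.00147589
    130	0.141093	0.0239317	0.000961958	0.138892	0.00123967
    150	0.134772	0.0247448	0.000509092	0.133506	0.000757
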
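energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	   1185	  25.43	25.4296	0.192268	1159.38
    1.5	  402.2	  25.43	25.4294	0.191895	376.579
 1.5596	  362.1	  25.43	25.4294	0.191851	336.479
 1.5596	   3957	  25.43	25.4294	0.191851	3931.38
      2	   2263	  25.43	25.4293	0.191524	2237.38
    2.5	1266.32	  25.43	25.4291	0.191155	1240.69
      3	    788	  25.43	25.4289	0.190788	 762.38
      4	  360.5	  25.43	25.4285	0.190058	334.881
      5	  193.4	  25.43	25.4282	0.189336	167.782
      6	  115.3	  25.43	25.4278	0.188622	89.6835
      8	  50.33	  25.43	25.4272	0.187213	24.7156
     10	  26.23	  25.43	25.4265	0.185831	0.617655
     12	15.3392	14.6744	14.6702	0.184477	0.484491
     15	  7.955	  7.487	7.48197	0.182492	0.290541
     18	4.67713	 4.2764	 4.2705	0.180564	0.226071
     20	  3.441	  3.094	3.08754	0.179308	0.174156
     25	1.86257	1.54673	1.53894	0.176268	0.147362
     28	1.36373	1.08766	1.07912	0.174509	0.110104
     30	  1.128	 0.8778	0.868779	0.173362	0.0858593
     32	0.967276	0.718757	0.709268	0.172235	0.0857722
     35	0.781368	0.544555	0.534389	0.170582	0.0763964
     40	 0.5685	 0.3601	0.34887	0.16792	0.0517102
     45	0.451954	0.252641	0.240418	0.165368	0.0461668
     50	 0.3681	  0.184	0.170852	0.16292	0.0343278
     55	0.317737	0.140545	0.126532	0.16057	0.0306351
     60	 0.2778	 0.1099	0.0950786	0.158311	0.0244107
     65	0.254162	0.0906969	0.0751185	0.156138	0.0229054
     70	0.234073	0.0759226	0.0596348	0.154047	0.0203921
     75	0.216801	0.0643399	0.0473866	0.152032	0.0173829
     80	 0.2018	0.05511	0.0375319	0.15009	0.0141786
     90	0.184566	0.0452534	0.0265355	0.146407	0.0116232
    100	 0.1704	0.03794	0.0182118	0.14297	0.00921794
    110	0.162103	0.0354049	0.0147782	0.139755	0.00757038
    120	0.154882	0.0332387	0.0118106	0.136739	0.00633282
    130	0.148524	0.0313632	0.00921831	0.133904	0.00540189
    150	 0.1378	0.02827	0.00490465	0.128711	0.00418388
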
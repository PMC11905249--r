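energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	292.902	291.875	291.874	0.179811	0.847574
    1.5	293.045	291.596	291.596	0.179462	1.27015
      2	293.189	291.319	291.318	0.179115	1.69192
    2.5	187.914	186.383	186.382	0.17877	1.35309
      3	130.668	129.364	129.363	0.178426	1.12697
      4	75.5605	74.5185	74.5172	0.177744	0.865561
      5	240.048	 236.44	236.438	0.177069	3.43296
      6	165.293	162.291	162.289	 0.1764	2.82763
      8	89.7339	87.5281	87.5255	0.175083	2.03332
     10	62.5639	60.6327	60.6295	0.173791	1.76062
     12	37.4952	36.0698	36.0659	0.172524	1.25678
     15	20.0622	 19.066	19.0613	0.170668	0.83028
     18	 12.301	 11.535	11.5295	0.168865	0.602649
     20	9.27977	8.61796	8.61192	0.16769	0.500163
     25	4.92417	4.44448	4.43719	0.164847	0.322129
     28	3.57712	3.16519	3.15721	0.163202	0.25671
     30	2.94754	2.57064	 2.5622	0.162129	0.223211
     32	 2.4894	2.13923	2.13036	0.161076	0.197963
     35	1.97156	1.65436	1.64486	0.15953	0.167177
     40	1.39764	  1.122	 1.1115	0.15704	0.129107
     45	1.02987	0.785495	0.774065	0.154654	0.101151
     50	0.786991	0.566461	0.554164	0.152364	0.0804619
     55	0.633999	0.430305	 0.4172	0.150166	0.0666328
     60	0.521983	0.332307	0.318446	0.148053	0.0554841
     65	0.444762	0.265875	0.251306	0.146022	0.0474349
     70	0.384187	0.21479	0.199557	0.144066	0.0405646
     75	0.335769	0.174821	0.158966	0.142181	0.0346216
     80	0.296429	0.143083	0.126643	0.140365	0.0294207
     90	0.249634	0.106864	0.089359	0.136921	0.0233541
    100	0.214251	0.0808683	0.0624184	0.133707	0.0181257
    110	0.195228	0.0681962	0.048906	 0.1307	0.015622
    120	0.179231	0.0581211	0.0380814	0.127879	0.0132702
    130	0.165566	0.0499934	0.0292833	0.125228	0.0110546
    150	0.143363	0.0378667	0.0160152	0.120372	0.00697598
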
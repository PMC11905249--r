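energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	20.4572	20.1614	 20.161	0.197026	0.0991771
    1.5	20.5061	20.1613	20.1607	0.196644	0.148764
      2	20.5551	20.1613	20.1605	0.196264	0.19835
    2.5	20.6041	20.1612	20.1603	0.195885	0.247934
      3	20.6531	20.1612	  20.16	0.195509	0.297518
      4	 20.751	20.1611	20.1596	0.194762	0.396681
      5	 20.849	 20.161	20.1591	0.194022	0.49584
      6	 20.947	20.1609	20.1587	0.193289	0.594995
      8	 21.143	20.1607	20.1578	0.191846	0.793293
     10	 21.339	20.1606	 20.157	0.19043	0.991575
     12	12.4511	11.5828	11.5786	0.189042	0.683498
     15	6.49277	 5.8776	5.87244	0.187008	0.433321
     18	3.81923	3.34463	3.33858	0.185032	0.29562
     20	2.82835	2.41434	2.40772	0.183745	0.236884
     25	1.52382	1.20408	1.19609	0.18063	0.147098
     28	1.13049	0.845204	0.836453	0.178827	0.115212
     30	0.948745	0.681175	0.671931	0.177652	0.0991621
     32	0.811505	0.558366	0.548643	0.176498	0.0863654
     35	0.658951	0.423451	0.413034	0.174803	0.0711138
     40	0.493314	0.279929	0.268421	0.172075	0.0528174
     45	0.395599	0.197677	0.185152	0.169461	0.0409864
     50	0.330141	0.144447	0.130974	0.166952	0.0322147
     55	0.287991	0.11152	0.0971603	0.164543	0.0262876
     60	0.256375	0.0878795	0.0726913	0.162228	0.0214553
     65	0.236229	0.0737228	0.0577588	0.160002	0.0184685
     70	0.219624	0.0626353	0.0459444	0.157859	0.0158209
     75	0.205642	0.0537865	0.0364137	0.155794	0.0134347
     80	0.193637	0.0465975	0.0285844	0.153804	0.0112491
     90	0.179293	0.0394639	0.0202828	0.15003	0.00897988
    100	0.167151	0.0340527	0.0138363	0.146508	0.00680644
    110	0.16051	0.0323605	0.0112234	0.143213	0.00607322
    120	0.154375	0.0309201	0.00896181	0.140123	0.00529026
    130	0.148673	0.02968	0.00698713	0.137217	0.0044683
    150	0.138352	0.0276578	0.00371427	0.131897	0.00274072
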
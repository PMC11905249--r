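energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	3673.06	 6.6257	6.62528	0.219676	3666.22
    1.5	 1236.2	6.62387	6.62323	0.21925	1229.36
      2	554.662	6.62204	6.62119	0.218826	547.822
    2.5	292.353	5.92639	5.92533	0.218404	286.209
      3	173.327	5.54251	5.54125	0.217984	167.567
      4	74.5792	5.16277	 5.1611	0.217151	 69.201
      5	40.1173	6.25928	6.25721	0.216326	33.6437
      6	23.3543	5.76503	5.76256	0.215509	17.3763
      8	10.1344	5.25441	5.25118	 0.2139	4.66937
     10	5.45971	5.06331	5.05933	0.212322	0.188061
     12	3.24389	2.86134	2.85664	0.210774	0.176484
     15	1.72527	1.42365	 1.4179	0.208507	0.0988564
     18	1.08834	0.803505	0.796759	0.206303	0.0852787
     20	0.837376	0.577614	0.570228	0.204868	0.0622793
     25	0.540553	0.289249	0.280349	0.201394	0.0588101
     28	0.436005	0.203836	0.194079	0.199385	0.0425411
     30	0.383579	0.164839	0.154532	0.198075	0.0309718
     32	0.354049	0.137422	0.126581	0.196787	0.0306808
     35	0.317501	0.106887	0.0952726	0.194898	0.0273302
     40	0.271202	0.0737874	0.0609564	0.191857	0.0183888
     45	0.246921	0.0562591	0.0422944	0.188942	0.0156852
     50	0.22761	0.0443846	0.0293622	0.186145	0.0121032
     55	0.215756	0.0379965	0.0219862	0.183459	0.0103108
     60	0.205642	0.0331176	0.0161833	0.180878	0.00858121
     65	0.198918	0.0309633	0.0131642	0.178395	0.00735805
     70	0.192932	0.0291687	0.0105591	0.176006	0.00636759
     75	0.187549	0.027652	0.0082821	0.173704	0.00556344
     80	0.182672	0.0263547	0.00627084	0.171485	0.00491669
     90	0.175635	0.025898	0.00451188	0.167277	0.0038456
    100	0.16955	0.0255517	0.00301124	0.163351	0.00318817
    110	0.164625	0.025987	0.00242004	0.159677	0.00252788
    120	0.160222	0.0263969	0.00191424	0.156231	0.00207656
    130	0.156248	0.0267826	0.00148096	0.152992	0.00177528
    150	0.149331	0.0274881	0.000792055	0.147059	0.0014798
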
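energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	 131.09	 130.45	130.449	0.199157	0.441491
    1.5	 131.23	 130.37	 130.37	0.19877	0.661832
      2	 131.37	130.291	 130.29	0.198386	0.881903
    2.5	99.0099	97.9838	97.9829	0.198004	0.829029
      3	78.6025	 77.618	77.6168	0.197623	0.788056
      4	55.5247	54.5904	54.5888	0.196868	0.738999
      5	116.168	114.044	114.042	0.19612	1.92981
      6	91.7155	89.7009	89.6987	0.195379	1.82145
      8	62.3215	60.4927	60.4898	0.19392	1.63777
     10	49.6684	47.8599	47.8563	0.192489	1.61964
     12	29.4893	 28.159	28.1547	0.191086	1.14344
     15	15.6242	14.6946	14.6894	0.189031	0.74572
     18	9.41756	8.70661	 8.7005	0.187033	0.530025
     20	7.04305	6.42928	6.42259	0.185732	0.43473
     25	3.72893	3.27776	 3.2697	0.182583	0.276648
     28	2.71428	2.32306	2.31422	0.180761	0.219302
     30	2.24237	  1.882	1.87266	0.179573	0.190134
     32	1.89269	 1.5566	1.54677	0.178406	0.167515
     35	1.50064	1.19426	1.18373	0.176693	0.140217
     40	1.07085	0.801608	0.789976	0.173936	0.106943
     45	0.802825	0.560724	0.548063	0.171293	0.0834686
     50	0.626295	0.404938	0.391319	0.168757	0.0662187
     55	0.513693	0.307373	0.292858	0.166322	0.0545129
     60	0.431389	0.237624	0.222272	0.163983	0.0451352
     65	0.375817	0.191618	0.175482	0.161732	0.0386033
     70	0.331908	0.156205	0.139333	0.159566	0.0330091
     75	0.296519	0.128453	0.110892	0.157479	0.0281477
     80	0.267494	0.106366	0.0881581	0.155467	0.0238689
     90	0.232862	0.0816376	0.0622492	0.151652	0.0189608
    100	0.20592	0.0636405	0.0432056	0.148092	0.0146224
    110	0.19181	0.0556501	0.0342845	0.144762	0.0127635
    120	0.179531	0.0491445	0.0269487	0.141638	0.0109446
    130	0.168703	0.043773	0.0208347	0.138701	0.00916665
    150	0.150332	0.0354841	0.0112817	0.133323	0.00572722
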
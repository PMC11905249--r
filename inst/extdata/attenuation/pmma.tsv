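energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	2793.87	3.02614	3.02572	0.215239	2790.63
    1.5	915.269	3.02614	3.02551	0.214822	912.028
      2	403.939	3.02614	3.02531	0.214406	400.699
    2.5	210.513	3.02614	3.02511	0.213993	207.273
      3	123.618	3.02614	 3.0249	0.213582	120.379
      4	52.4709	3.02614	 3.0245	0.212765	49.2336
      5	26.9306	3.02614	3.02411	0.211957	23.6946
      6	15.4542	3.02614	3.02372	0.211157	12.2193
      8	6.49354	3.02614	3.02297	0.20958	3.26099
     10	3.35682	3.02614	3.02224	0.208033	0.12655
     12	2.02817	1.69344	1.68882	0.206517	0.132831
     15	1.10126	0.832456	0.826822	0.204295	0.0701459
     18	0.724746	0.465486	0.458876	0.202136	0.0637335
     20	0.57139	0.332826	0.32559	0.20073	0.0450697
     25	0.400904	0.167935	0.159214	0.197327	0.044363
     28	0.336625	0.118894	0.109334	0.195358	0.0319335
     30	0.303215	0.0964567	0.0863577	0.194074	0.0227836
     32	0.286079	0.0814933	0.0708708	0.192813	0.022395
     35	0.264133	0.0646189	0.053239	0.190962	0.0199321
     40	0.234999	0.0459861	0.0334142	0.187982	0.0136026
     45	0.219933	0.0370056	0.023323	0.185125	0.011485
     50	0.207394	0.0306675	0.0159485	0.182385	0.00906029
     55	0.199384	0.0276736	0.0119866	0.179754	0.00764396
     60	0.192359	0.0252948	0.00870255	0.177225	0.00643196
     65	0.187405	0.0245964	0.0071568	0.174792	0.00545582
     70	0.182925	0.0239973	0.00576355	0.172451	0.00471017
     75	0.178841	0.0234776	0.00449887	0.170196	0.00414709
     80	0.175101	0.0230228	0.00334456	0.168021	0.00373526
     90	0.16922	0.0233628	0.00240867	0.163899	0.00291261
    100	 0.1641	0.023678	0.00159287	0.160051	0.00245532
    110	0.159604	0.0243424	0.00125144	0.156452	0.0019013
    120	0.155586	0.0249583	0.000970212	0.153075	0.00154069
    130	0.15196	0.0255324	0.000741802	0.149902	0.00131699
    150	0.14565	0.0265753	0.00041838	0.144089	0.00114221
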
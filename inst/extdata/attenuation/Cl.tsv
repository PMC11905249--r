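energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	200.796	199.979	199.979	0.191369	0.625513
    1.5	 200.95	199.822	199.821	0.190998	0.93753
      2	201.104	199.665	199.664	0.190628	1.24906
    2.5	139.438	138.168	138.167	0.190261	1.08043
      3	  103.4	102.252	102.251	0.189895	0.959488
      4	65.8925	64.8929	64.8915	0.189169	0.811895
      5	170.918	168.102	  168.1	0.188451	  2.629
      6	125.768	123.269	123.267	0.187739	2.31339
      8	76.1353	74.0977	74.0948	0.186337	1.85409
     10	 56.642	54.7481	54.7447	0.184962	1.71236
     12	33.7905	32.3952	32.3911	0.183614	1.21579
     15	17.9921	17.0173	17.0123	0.181639	0.798188
     18	 10.939	10.1917	10.1858	0.179719	0.573482
     20	8.21652	7.57125	7.56481	0.178469	0.473239
     25	4.35351	3.88281	3.87505	0.175443	0.303019
     28	3.16471	2.75866	2.75016	0.173692	0.240862
     30	2.61042	2.23771	2.22873	0.172551	0.209137
     32	2.20347	 1.8566	1.84715	0.17143	0.184887
     35	1.74532	1.43019	1.42008	0.169784	0.155465
     40	1.24028	0.964987	0.953809	0.167134	0.119337
     45	0.920943	0.675189	0.663024	0.164595	0.0933241
     50	0.71035	0.48714	0.474053	0.162158	0.0741394
     55	 0.5769	0.369808	0.355861	0.159819	0.0612203
     60	0.479287	0.285632	0.27088	0.15757	0.050837
     65	0.41269	0.229317	0.213811	0.155408	0.0434707
     70	0.360275	0.185987	0.169776	0.153326	0.0371729
     75	0.318217	0.152057	0.135183	0.151321	0.031713
     80	0.283895	0.125082	0.107586	0.149387	0.0269214
     90	0.243039	0.0945693	0.075939	0.145722	0.0213776
    100	0.211722	0.0725164	0.0528805	0.142301	0.0165405
    110	0.195133	0.0622188	0.0416887	0.139101	0.0143438
    120	0.18095	0.0539381	0.0326102	0.136099	0.0122402
    130	0.168643	0.0471831	0.0251419	0.133277	0.0102233
    150	0.148214	0.03694	0.0136839	0.128109	0.00642028
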
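energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	537.074	6.34357	 6.3432	0.191522	 530.54
    1.5	174.226	6.34355	6.34299	0.191151	167.692
      2	 78.846	6.34352	6.34278	0.190781	72.3124
    2.5	 43.478	 6.3435	6.34258	0.190413	 36.945
      3	27.8072	6.34347	6.34237	0.190047	21.2747
      4	15.2265	6.34342	6.34197	0.189321	8.69517
      5	10.7856	6.34338	6.34157	0.188602	4.25539
      6	 8.8642	6.34333	6.34118	0.18789	2.33513
      8	7.41514	6.34324	6.34042	0.186486	0.888237
     10	6.96791	6.34315	6.33968	0.18511	0.443123
     12	4.07469	3.58301	3.57891	0.183761	0.312022
     15	2.14812	1.78075	1.77573	0.181784	0.190601
     18	1.30591	0.999979	0.994097	0.179863	0.131952
     20	0.991859	0.716269	0.70983	0.178612	0.103418
     25	0.590853	0.356125	0.348365	0.175584	0.0669045
     28	0.466235	0.249507	0.241001	0.173831	0.0514027
     30	0.407463	0.200813	0.191827	0.172689	0.0429466
     32	0.366252	0.16629	0.156838	0.171567	0.0378469
     35	0.319034	0.127887	0.117761	0.16992	0.031353
     40	0.265157	0.0862814	0.0750948	0.167268	0.022794
     45	0.234654	0.0642194	0.0520445	0.164727	0.0178834
     50	0.212326	0.0492234	0.0361263	0.162288	0.0139117
     55	0.198376	0.0409465	0.026988	0.159947	0.0114412
     60	0.186804	0.0346052	0.0198413	0.157696	0.00926626
     65	0.179737	0.0316343	0.0161163	0.155532	0.00808857
     70	0.173344	0.0291439	0.0129193	0.153449	0.00697575
     75	0.167491	0.0270255	0.0101381	0.151442	0.00591124
     80	0.162075	0.0251972	0.00768728	0.149507	0.00488073
     90	0.155288	0.0241701	0.00552486	0.145839	0.00392447
    100	0.149078	0.0233368	0.00368521	0.142415	0.00297709
    110	0.144768	0.0235165	0.00296988	0.139212	0.00258611
    120	0.140781	0.0236988	0.00235392	0.136208	0.00221939
    130	0.137079	0.0238826	0.00182368	0.133384	0.00187083
    150	0.130405	0.0242513	0.000976647	0.128212	0.00121601
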
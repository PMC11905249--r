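energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	  7.217	0.00986	0.00908858	0.395893	6.81202
    1.5	  2.148	0.00986	0.00870758	0.395125	1.74417
      2	  1.059	0.00986	0.00832969	0.394361	0.656309
    2.5	0.746662	0.00986	0.00795486	0.393601	0.345107
      3	 0.5612	0.00986	0.00758307	0.392844	0.160772
      4	 0.4546	0.00986	0.00684848	0.391343	0.0564086
      5	 0.4193	0.00986	0.00612568	0.389856	0.0233181
      6	 0.4042	0.00986	0.00541442	0.388384	0.0104013
      8	 0.3914	0.00986	0.00402566	0.385484	0.00189077
     10	 0.3854	0.00986	0.00268041	0.382639	8.04387e-05
     12	0.381327	0.00996035	0.00147734	0.379849	  1e-08
     15	 0.3764	0.0109994	0.000636111	0.375764	  1e-08
     18	0.372012	0.0123775	0.000219327	0.371793	  1e-08
     20	 0.3695	0.0133097	  1e-08	0.369207	0.00029309
     25	0.362947	0.0160406	  1e-08	0.362947	  1e-08
     28	0.359325	0.0175838	  1e-08	0.359325	  1e-08
     30	  0.357	 0.0186	2.47136e-05	0.356964	1.16592e-05
     32	0.354644	0.0195382	  1e-08	0.354644	  1e-08
     35	0.35124	0.0209312	  1e-08	0.35124	  1e-08
     40	 0.3458	0.0231237	  1e-08	0.345758	4.16802e-05
     45	0.340504	0.0251667	  1e-08	0.340504	  1e-08
     50	 0.3355	 0.0271	2.71224e-05	0.335464	9.10524e-06
     55	0.330624	0.0288534	  1e-08	0.330624	  1e-08
     60	  0.326	0.0305183	  1e-08	0.325972	2.77199e-05
     65	0.321498	0.032077	  1e-08	0.321498	  1e-08
     70	0.317192	0.0335377	  1e-08	0.317192	  1e-08
     75	0.313044	0.0349079	  1e-08	0.313044	  1e-08
     80	 0.3091	 0.0362	5.46467e-06	0.309044	5.02077e-05
     90	0.301462	0.0385414	  1e-08	0.301462	  1e-08
    100	 0.2944	0.0406216	  1e-08	0.294385	1.48586e-05
    110	0.287764	0.0424716	  1e-08	0.287764	  1e-08
    120	0.281554	0.0441218	  1e-08	0.281554	  1e-08
    130	0.275717	0.0455978	  1e-08	0.275717	  1e-08
    150	 0.2651	0.0481108	  1e-08	0.265025	7.45897e-05
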
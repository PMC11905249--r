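energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	    986	983.616	983.616	0.183411	2.20045
    1.5	    986	 982.52	 982.52	0.183055	  3.297
      2	    986	981.427	981.426	0.182701	4.39111
    2.5	534.417	531.264	531.263	0.182349	2.97123
      3	    324	 321.66	321.659	0.181998	2.15876
      4	    150	148.491	 148.49	0.181303	1.32875
 4.9664	   83.8	82.7023	82.7006	0.180637	0.918833
 4.9664	  687.8	680.065	680.063	0.180637	7.55575
      5	676.503	 536.75	668.841	0.180614	7.48134
      6	  432.3	356.223	426.397	0.179932	5.72336
      8	  202.3	 174.06	198.568	0.178588	3.55373
     10	  110.7	97.4327	108.104	0.17727	2.41841
     12	66.6924	59.4509	64.7775	0.175978	1.73897
     15	  35.87	32.2682	 34.537	0.174085	1.15894
     18	21.3764	19.2708	20.3834	0.172246	0.820796
     20	  15.85	14.2727	15.0075	0.171048	0.671466
     25	8.37402	7.47173	7.77125	0.168147	0.434627
     28	6.05627	5.35529	5.54261	0.166469	0.347183
     30	  4.972	4.36467	4.50433	0.165375	0.302299
     32	4.14676	3.61078	3.71641	0.164301	0.266048
     35	3.22302	 2.7677	2.83808	0.162724	0.222218
     40	  2.214	 1.8493	1.88513	0.160184	0.168689
     45	1.61156	1.30351	1.32084	0.15775	0.132968
     50	  1.213	0.944947	0.95119	0.155415	0.106396
     55	0.953962	0.71362	0.713055	0.153173	0.0877348
     60	 0.7661	0.547506	0.542292	0.151018	0.0727899
     65	0.641685	0.438511	0.430186	0.148945	0.0625541
     70	0.544583	0.354484	0.343796	0.14695	0.0538375
     75	0.467439	0.288626	0.276089	0.145028	0.0463229
     80	 0.4052	0.236274	0.222249	0.143175	0.0397756
     90	0.328386	0.173227	0.157095	0.139662	0.0316294
    100	 0.2721	0.12863	0.110905	0.136384	0.0248107
    110	0.24188	0.106018	0.0871241	0.133316	0.0214396
    120	0.217232	0.0883018	0.0684239	0.13044	0.0183686
    130	0.196782	0.0742091	0.0534907	0.127735	0.0155564
    150	 0.1649	0.0536171	0.0315357	0.122782	0.0105823
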
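energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	 478.95	477.464	477.464	0.193927	 1.2924
    1.5	479.063	476.934	476.933	0.193551	1.93644
      2	479.176	476.404	476.404	0.193176	2.57906
    2.5	285.108	283.001	    283	0.192804	1.91506
      3	186.554	184.861	 184.86	0.192433	1.50114
      4	98.4043	97.1621	97.1606	0.191698	1.05198
      5	378.725	373.482	 373.48	0.19097	5.05467
      6	244.919	 240.82	240.818	0.190248	3.91107
      8	119.942	117.218	117.215	0.188828	2.53821
     10	 78.646	76.3944	76.3909	0.187434	2.06775
     12	47.3424	 45.677	45.6728	0.186068	1.48353
     15	25.4519	24.2871	 24.282	0.184066	0.985897
     18	15.7342	14.8355	14.8296	0.182121	0.722533
     20	11.9208	11.1436	11.1371	0.180855	0.602915
     25	6.33817	5.77779	5.76993	0.177788	0.390451
     28	 4.6034	4.12409	4.11548	0.176014	0.311914
     30	3.79074	3.35341	3.34431	0.174857	0.271572
     32	3.20442	2.79868	2.78911	0.173721	0.241586
     35	2.53915	 2.1725	2.16225	0.172053	0.204847
     40	1.79799	1.48084	1.46952	0.169368	0.159107
     45	1.31685	1.03751	1.02518	0.166795	0.124874
     50	0.998627	0.748108	0.734847	0.164326	0.0994541
     55	0.799276	0.568869	0.554736	0.161955	0.0825857
     60	0.653154	0.43948	0.424531	0.159676	0.0689471
     65	0.551379	0.350673	0.33496	0.157485	0.0589336
     70	0.471772	0.282425	0.265997	0.155375	 0.0504
     75	0.408357	0.229079	0.21198	0.153343	0.043034
     80	0.35703	0.186771	0.169041	0.151384	0.0366048
     90	0.295952	0.138114	0.119235	0.14767	0.0290471
    100	0.250345	0.103429	0.0835311	0.144203	0.0226102
    110	0.225402	0.0858728	0.0650682	0.14096	0.0193739
    120	0.204752	0.0720608	0.0504479	0.137918	0.0163863
    130	0.187372	0.0610326	0.0386967	0.135059	0.0136168
    150	0.159714	0.0448274	0.0212605	0.129822	0.00863218
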
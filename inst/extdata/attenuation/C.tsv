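energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	   2211	  2.078	2.07761	0.199347	2208.72
    1.5	  700.2	  2.078	2.07742	0.198961	697.924
      2	    303	  2.078	2.07723	0.198576	300.724
    2.5	 155.66	  2.078	2.07704	0.198193	153.385
      3	  90.33	  2.078	2.07685	0.197812	88.0553
      4	  37.78	  2.078	2.07648	0.197056	35.5065
      5	  19.12	  2.078	2.07612	0.196308	16.8476
      6	  10.95	  2.078	2.07576	0.195566	8.67867
      8	  4.576	  2.078	2.07506	0.194106	2.30683
     10	  2.373	  2.078	2.07438	0.192674	0.105942
     12	1.46113	1.15484	1.15057	0.191269	0.119296
     15	 0.8071	 0.5627	0.557482	0.189212	0.0604067
     18	0.551056	0.313696	0.307574	0.187212	0.0562704
     20	  0.442	 0.2238	0.217098	0.18591	0.0389921
     25	 0.3274	0.114423	0.106346	0.182758	0.0382962
     28	0.281112	0.0813851	0.072531	0.180934	0.0276474
     30	 0.2562	0.06614	0.0567866	0.179745	0.0196685
     32	0.244391	0.0567526	0.0469144	0.178577	0.0188998
     35	0.228891	0.0458861	0.0353464	0.176863	0.0166823
     40	 0.2076	0.03343	0.0217863	0.174103	0.0117111
     45	0.196514	0.0280466	0.0153742	0.171457	0.00968285
     50	 0.1871	0.02397	0.0103378	0.168919	0.00784334
     55	0.180836	0.0223573	0.00782855	0.166482	0.00652531
     60	 0.1753	0.02098	0.00561285	0.16414	0.00554759
     65	0.171198	0.0208085	0.00465646	0.161887	0.00465505
     70	0.167486	0.0206509	0.00376339	0.159718	0.00400463
     75	0.164103	0.0205053	0.00292781	0.157629	0.00354575
     80	  0.161	0.02037	0.00214466	0.155616	0.00323965
     90	0.155859	0.0209434	0.00153636	0.151797	0.00252545
    100	 0.1514	0.02147	0.00101546	0.148234	0.00215032
    110	0.147297	0.0221446	0.000758495	 0.1449	0.00163836
    120	0.143649	0.0227789	0.000561909	0.141773	0.00131343
    130	0.140372	0.0233785	0.000418265	0.138834	0.00112018
    150	 0.1347	0.02449	0.000264367	0.13345	0.000985161
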
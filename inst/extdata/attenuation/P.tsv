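energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	77.4636	76.9873	 76.987	0.193256	0.283357
    1.5	77.5721	76.9549	76.9543	0.192881	0.424856
      2	77.6805	76.9225	76.9218	0.192508	0.566235
    2.5	63.9792	63.2064	63.2055	0.192137	0.581583
      3	54.6147	53.8297	53.8286	0.191768	0.594362
      4	43.0474	42.2361	42.2346	0.191035	0.621792
      5	71.6558	70.1759	70.1741	0.190309	1.29141
      6	60.9743	59.4736	59.4714	0.18959	1.31334
      8	46.8526	45.3326	45.3298	0.188174	1.33472
     10	40.1774	38.5745	 38.571	0.186786	1.41964
     12	23.7366	22.5592	 22.555	0.185424	0.996188
     15	12.5135	  11.69	 11.685	0.18343	0.645112
     18	7.47655	6.84772	6.84178	0.181491	0.453272
     20	5.56758	5.02446	5.01797	0.180229	0.369381
     25	2.94857	 2.5457	2.53787	0.177173	0.233522
     28	2.15104	1.79963	1.79105	0.175405	0.184579
     30	1.78105	1.45608	1.44702	0.174252	0.159776
     32	1.50425	1.20041	1.19087	0.17312	0.14026
     35	1.19525	0.917174	0.906957	0.171458	0.116835
     40	0.858426	0.61243	0.601142	0.168782	0.0885022
     45	0.651337	0.428472	0.416187	0.166218	0.0689316
     50	0.515087	0.309939	0.296724	0.163757	0.0546059
     55	0.427544	0.235427	0.221343	0.161394	0.0448069
     60	0.36358	0.18237	0.167472	0.159124	0.0369837
     65	0.320826	0.147906	0.132248	0.15694	0.0316387
     70	0.28689	0.121372	  0.105	0.154838	0.0270524
     75	0.259395	0.100566	0.083526	0.152813	0.0230568
     80	0.236715	0.0839938	0.0663254	0.15086	0.0195293
     90	0.20953	0.0656655	0.0468515	0.147159	0.0155197
    100	0.188037	0.0522346	0.0324051	0.143705	0.011927
    110	0.176849	0.046626	0.0258934	0.140472	0.0104833
    120	0.166935	0.0419965	0.0204584	0.137441	0.00903585
    130	0.158046	0.0381223	0.0158637	0.134591	0.0075904
    150	0.142632	0.0320285	0.00854315	0.129373	0.00471657
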
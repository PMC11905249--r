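energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	1070.72	7.66696	7.66657	0.199205	1062.85
    1.5	365.696	7.66344	7.66286	0.198818	357.835
      2	167.697	7.65993	7.65916	0.198434	 159.84
    2.5	90.1821	6.31398	6.31302	0.198051	 83.671
      3	54.8668	5.58265	 5.5815	0.197671	49.0877
      4	25.4495	4.87925	4.87773	0.196915	20.3749
      5	17.1801	6.95631	6.95443	0.196167	10.0295
      6	11.4778	6.00532	6.00308	0.195426	5.27934
      8	6.83384	5.04652	5.04359	0.193967	1.59629
     10	5.21974	4.70173	4.69811	0.192535	0.329091
     12	3.09222	2.66899	2.66472	0.191132	0.236367
     15	  1.663	1.33554	1.33032	0.189076	0.143604
     18	1.04195	0.75906	0.752942	0.187078	0.101932
     20	0.806531	0.548001	0.541304	0.185777	0.0794503
     25	0.50463	0.275425	0.267354	0.182627	0.0546488
     28	0.407939	0.194514	0.185666	0.180804	0.0414685
     30	0.36165	0.157533	0.148186	0.179616	0.0338473
     32	0.330628	0.131389	0.121558	0.178449	0.0306213
     35	0.29428	0.102281	0.0917493	0.176736	0.0257947
     40	0.251469	0.0707612	0.0591258	0.173978	0.0183651
     45	0.227085	0.0536889	0.0410256	0.171334	0.0147248
     50	0.208737	0.042222	0.0285996	0.168798	0.0113398
     55	0.197235	0.035948	0.0214297	0.166362	0.00944328
     60	0.187532	0.0312077	0.0158516	0.164022	0.00765882
     65	0.181319	0.0289871	0.0128467	0.161771	0.00670185
     70	0.175691	0.0271671	0.0102917	0.159604	0.00579526
     75	0.170531	0.0256523	0.00808741	0.157517	0.00492738
     80	0.165756	0.0243745	0.00616221	0.155504	0.00408943
     90	0.159391	0.0238188	0.00442569	0.151689	0.00327706
    100	0.153618	0.02341	0.0029701	0.148128	0.00252035
    110	0.149332	0.0237545	0.00238375	0.144796	0.00215206
    120	0.145388	0.0240858	0.00188475	0.141672	0.00183102
    130	0.141739	0.024402	0.0014582	0.138734	0.00154601
    150	0.13519	0.0249866	0.000778364	0.133355	0.00105676
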
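energy_keV	mu_total	mu_en	mu_pe	mu_incoh	mu_coh
      1	15.0543	14.7823	 14.782	0.190938	0.0814249
    1.5	15.0944	14.7823	14.7817	0.190568	0.122135
      2	15.1345	14.7822	14.7815	0.190199	0.162844
    2.5	15.1746	14.7821	14.7812	0.189832	0.203552
      3	15.2147	14.7821	 14.781	0.189468	0.244259
      4	15.2949	 14.782	14.7805	0.188743	0.325668
      5	15.3751	14.7818	  14.78	0.188026	0.407072
      6	15.4554	14.7817	14.7796	0.187316	0.488471
      8	15.6159	14.7815	14.7787	0.185917	0.651255
     10	15.7764	14.7813	14.7778	0.184546	0.814021
     12	9.18962	8.45209	  8.448	 0.1832	0.558419
     15	4.79194	4.26382	4.25882	0.18123	0.351889
     18	2.82917	2.41668	2.41082	0.179314	0.239035
     20	2.10298	1.74031	1.73389	0.178067	0.19102
     25	1.15147	0.865969	0.858233	0.175048	0.118187
     28	0.864023	0.606905	0.598424	0.173301	0.092298
     30	0.730982	0.488529	0.47957	0.172162	0.0792499
     32	0.631717	0.401063	0.391639	0.171044	0.0690338
     35	0.520774	0.304674	0.294579	0.169402	0.056793
     40	0.399227	0.201648	0.190496	0.166758	0.0419731
     45	0.328363	0.143672	0.131534	0.164224	0.0326044
     50	0.279874	0.105639	0.092582	0.161793	0.0254989
     55	0.249109	0.0827206	0.0688048	0.159459	0.0208452
     60	0.225382	0.0659529	0.051234	0.157215	0.016933
     65	0.210686	0.0564326	0.040962	0.155058	0.0146663
     70	0.198225	0.0488287	0.0326536	0.152981	0.0125908
     75	0.187449	0.0426433	0.0258073	0.15098	0.0106618
     80	0.177955	0.0375191	0.0200626	0.149051	0.00884104
     90	0.166771	0.0328805	0.0142921	0.145394	0.0070854
    100	0.157002	0.0292772	0.00968556	0.141981	0.00533519
    110	 0.1514	0.0283373	0.00785333	0.138788	0.00475852
    120	0.146199	0.0275446	0.00626484	0.135793	0.00414111
    130	0.141349	0.0268702	0.0048786	0.132977	0.00349353
    150	0.132553	0.0257946	0.00259093	0.127821	0.00214078
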
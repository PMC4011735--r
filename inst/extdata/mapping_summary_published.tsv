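library_id	section	total_reads	total_mapped	perfect_match	one_mismatch	unique_match	multi_position_match	unmapped
1h-CK	genes	7218527	4338614	3303737	1034877	4203040	135574	2879913
1h-DA	genes	7059269	3976792	3026423	950369	3846164	130628	3082477
4h-CK	genes	7607918	4208364	3210421	997943	4062080	146284	3399554
4h-DA	genes	7262556	3972549	3025332	947217	3825954	146595	3290007
8h-CK	genes	7371616	4119567	3128946	990621	3984631	134936	3252049
8h-DA	genes	7270371	4069945	3071129	998816	3918331	151614	3200426
12h-CK	genes	7007499	4024328	3087657	936671	3879756	144572	2983171
12h-DA	genes	7447287	4387447	3332790	1054657	4226722	160725	3059840
24h-CK	genes	7322620	4381281	3351541	1029740	4231254	150027	2941339
24h-DA	genes	7218751	4388131	3327038	1061093	4209788	178343	2830620
1h-CK	genome	7218527	5753578	4188473	1565105	5258986	494592	1464949
1h-DA	genome	7059269	5633325	4095419	1537906	5137525	495800	1425944
4h-CK	genome	7607918	6092604	4449564	1643040	5538986	553618	1515314
4h-DA	genome	7262556	5814310	4235398	1578912	5277498	536812	1448246
8h-CK	genome	7371616	5914326	4293595	1620731	5367432	546894	1457290
8h-DA	genome	7270371	5815639	4200774	1614865	5260111	555528	1454732
12h-CK	genome	7007499	5643292	4145460	1497832	5121247	522045	1364207
12h-DA	genome	7447287	5991286	4365692	1625594	5420779	570507	1456001
24h-CK	genome	7322620	5893436	4322509	1570927	5335314	558122	1429184
24h-DA	genome	7218751	5811085	4226172	1584913	5240312	570773	1407666
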
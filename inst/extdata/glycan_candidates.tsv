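id	composition	subgroup	glycan_class	end_state	printed_mass	observed_mz
1	Hex_1_HexNAc_1_	Neutral	O	reduced	511.3	518.4
2	Hex_2_HexNAc_1_	Neutral	O	reduced	715.4	722.4
3	Hex_3_HexNAc_1_	Neutral	O	reduced	919.5	926.5
4	Hex_4_HexNAc_1_	Neutral	O	reduced	1123.6	568.7
5	HexA_1_Hex_1_HexNAc_1_	Charged	O	reduced	729.4	736.4
6	HexA_1_Hex_2_HexNAc_1_	Charged	O	reduced	933.5	940.6
7	HexA_1_Hex_3_HexNAc_1_	Charged	O	reduced	1137.6	575.6
8	HexA_1_Hex_4_HexNAc_1_	Charged	O	reduced	1341.7	677.6
9	dHex_1_Hex_1_HexNAc_1_	Neutral + Fucose(s)	O	reduced	685.4	692.5
10	dHex_1_Hex_2_HexNAc_1_	Neutral + Fucose(s)	O	reduced	889.5	896.5
11	dHex_1_Hex_4_HexNAc_1_	Neutral + Fucose(s)	O	reduced	1297.7	655.6
12	dHex_2_Hex_4_HexNAc_1_	Neutral + Fucose(s)	O	reduced	1471.8	742.7
13	dHex_2_Hex_5_HexNAc_1_	Neutral + Fucose(s)	O	reduced	1675.9	565.4
14	dHex_2_Hex_2_HexNAc_2_	Neutral + Fucose(s)	O	reduced	1308.7	661.5
15	dHex_1_Hex_3_HexNAc_1_	Neutral + Fucose(s)	O	reduced	1093.6	553.7
16	HexA_1_dHex_1_Hex_1_HexNAc_1_	Charged + Fucose(s)	O	reduced	903.5	910.5
17	HexA_1_dHex_1_Hex_2_HexNAc_1_	Charged + Fucose(s)	O	reduced	1107.6	560.7
18	HexA_1_dHex_1_Hex_3_HexNAc_1_	Charged + Fucose(s)	O	reduced	1311.7	662.7
19	HexA_1_dHex_1_Hex_2_HexNAc_2_	Charged + Fucose(s)	O	reduced	1352.7	683.5
20	HexA_1_dHex_1_Hex_3_HexNAc_2_	Charged + Fucose(s)	O	reduced	1556.8	785.6
21	HexA_1_dHex_2_Hex_1_HexNAc_2_	Charged + Fucose(s)	O	reduced	1322.7	668.5
22	HexA_1_dHex_2_Hex_2_HexNAc_2_	Charged + Fucose(s)	O	reduced	1526.8	770.6
23	HexA_1_dHex_3_Hex_2_HexNAc_2_	Charged + Fucose(s)	O	reduced	1700.9	574.1
24	HexA_1_dHex_3_Hex_3_HexNAc_2_	Charged + Fucose(s)	O	reduced	1905.0	959.8
25	HexA_1_dHex_4_Hex_3_HexNAc_2_	Charged + Fucose(s)	O	reduced	2079.1	1046.8
26	HexA_1_dHex_4_Hex_4_HexNAc_2_	Charged + Fucose(s)	O	reduced	2283.2	767.9
27	HexA_1_dHex_4_Hex_5_HexNAc_2_	Charged + Fucose(s)	O	reduced	2487.3	836.4
28	HexA_1_dHex_5_Hex_4_HexNAc_2_	Charged + Fucose(s)	O	reduced	2457.3	826.3
29	HexA_1_dHex_5_Hex_5_HexNAc_2_	Charged + Fucose(s)	O	reduced	2661.4	894.2
30	Hex_5_HexNAc_2_	Oligomannosidic	N	free	1556.8	785.6
31	Hex_6_HexNAc_2_	Oligomannosidic	N	free	1760.9	887.3
32	Hex_7_HexNAc_2_	Oligomannosidic	N	free	1965.0	989.7
33	Hex_8_HexNAc_2_	Oligomannosidic	N	free	2169.1	1091.8
34	Hex_9_HexNAc_2_	Oligomannosidic	N	free	2373.2	798.4
35	Hex_10_HexNAc_2_	Oligomannosidic	N	free	2577.3	866.2
36	Hex_2_HexNAc_2_	Paucimannosidic	N	free	944.5	951.6
37	Hex_2_dHex_1_HexNAc_2_	Paucimannosidic	N	free	1118.6	566.5
38	Hex_2_dHex_2_HexNAc_2_	Paucimannosidic	N	free	1292.7	653.5
39	Hex_3_HexNAc_2_	Paucimannosidic	N	free	1148.6	581.4
40	Hex_3_dHex_1_HexNAc_2_	Paucimannosidic	N	free	1322.7	668.5
41	Hex_3_dHex_2_HexNAc_2_	Paucimannosidic	N	free	1496.8	755.6
42	Hex_4_HexNAc_2_	Paucimannosidic	N	free	1352.7	683.6
43	Hex_4_dHex_1_HexNAc_2_	Paucimannosidic	N	free	1526.8	770.6
44	Hex_4_dHex_2_HexNAc_2_	Paucimannosidic	N	free	1700.9	857.7
45	Hex_5_dHex_1_HexNAc_2_	Paucimannosidic	N	free	1730.9	872.7
46	Hex_5_dHex_2_HexNAc_2_	Paucimannosidic	N	free	1905.0	959.8
47	Hex_3_dHex_3_HexNAc_2_	Fucose-Rich	N	free	1670.9	842.7
48	Hex_4_dHex_3_HexNAc_2_	Fucose-Rich	N	free	1875.0	944.7
49	Hex_4_dHex_4_HexNAc_2_	Fucose-Rich	N	free	2049.1	1031.5
50	Hex_5_dHex_3_HexNAc_2_	Fucose-Rich	N	free	2079.1	700.0
51	Hex_5_dHex_4_HexNAc_2_	Fucose-Rich	N	free	2253.2	758.1
52	Hex_6_dHex_1_HexNAc_2_	Fucose-Rich	N	free	1935.0	974.7
53	Hex_6_dHex_3_HexNAc_2_	Fucose-Rich	N	free	2283.2	768.3
54	Hex_6_dHex_4_HexNAc_2_	Fucose-Rich	N	free	2457.2	826.4
55	Hex_7_dHex_1_HexNAc_2_	Fucose-Rich	N	free	2139.1	720.3
56	HexNAc_1_Hex_3_HexNAc_2_	Truncated Complex	N	free	1393.7	703.7
57	HexNAc_1_Hex_3_dHex_1_HexNAc_2_	Truncated Complex	N	free	1567.8	529.3
58	HexNAc_2_Hex_3_HexNAc_2_	Truncated Complex	N	free	1638.8	826.7
59	HexNAc_2_Hex_3_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1812.9	611.4
60	HexNAc_3_Hex_3_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2058.1	693.3
61	HexNAc_4_Hex_3_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2129.1	716.5
62	HexNAc_5_Hex_3_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2374.2	798.4
63	HexNAc_1_Hex_4_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1771.9	597.4
64	HexNAc_1_Hex_4_dHex_2_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1946.0	655.4
65	HexNAc_1_Hex_4_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1597.8	539.4
66	HexNAc_2_Hex_4_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1842.9	621.3
67	HexNAc_2_Hex_4_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2017.0	679.5
68	HexNAc_3_Hex_4_dHex_2_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2436.3	818.8
69	HexNAc_3_Hex_4_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2088.1	703.2
70	HexNAc_4_Hex_4_dHex_2_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2681.4	900.5
71	HexNAc_1_Hex_5_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1801.9	607.4
72	HexNAc_1_Hex_5_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	1976.0	665.5
73	HexNAc_1_Hex_5_dHex_2_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2150.1	723.5
74	HexNAc_3_Hex_5_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2292.2	770.8
75	HexNAc_3_Hex_5_dHex_2_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2640.4	886.9
76	HexNAc_1_Hex_6_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2006.0	675.5
77	HexNAc_1_Hex_6_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2180.1	733.4
78	HexNAc_1_Hex_7_dHex_1_HexNAc_2_	Complex or Hybrid with additional HexNAc(s)	N	free	2384.2	801.6
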
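node	degree	kshell	coreness_plus	mdd	kshell_if	h_index	hks	erm	gravity	sir_spread
1	16	4	250	11.2	534.5	5	7441	326.571	196	4.86
2	9	4	187	6.9	413.5	4	5021	235.639	124	4.03
3	10	4	226	7.6	505.5	5	5623	278.354	144	5.12
4	6	4	160	5.1	370.667	4	3728	183.816	88	3.89
5	3	3	71	3	173	3	1340	68.4286	30	2.46
6	4	3	77	3.4	185.5	3	1412	72.6049	36	2.87
7	4	3	77	3.4	185.5	3	1412	72.6049	36	2.94
8	4	4	138	4	329.333	4	2766	145.947	64	3
9	5	4	184	4.7	417.333	4	3243	190.896	80	4.17
10	2	2	84	2	178.667	2	1404	85.0739	16	2.24
11	3	3	71	3	173	3	1340	68.4286	30	2.3
12	1	1	49	1	130	1	752	44.5235	4	1.62
13	2	2	71	2	176	2	1344	71.9343	16	2.28
14	5	4	186	5	432	5	3387	190.304	80	3.96
15	2	2	83	2	162.667	2	1238	82.4038	16	2.4
16	2	2	83	2	162.667	2	1238	82.4038	16	2.86
17	2	2	24	2	44	2	602	25.0211	12	2.04
18	2	2	80	2	196	2	1391	77.8193	16	2.34
19	2	2	83	2	162.667	2	1238	82.4038	16	2.72
20	3	3	128	3	292.167	3	2012	122.177	36	2.84
21	2	2	83	2	162.667	2	1238	82.4038	16	2.19
22	2	2	80	2	196	2	1391	77.8193	16	2.77
23	2	2	83	2	162.667	2	1238	82.4038	16	2.29
24	5	3	119	4.1	240.167	4	2105	128.514	51	2.67
25	3	3	44	3	87	3	1109	55.3571	27	2.24
26	3	3	47	3	93	3	1123	56.9549	27	2.31
27	2	2	61	2	116.667	2	980	62.5179	14	1.92
28	4	3	110	3.7	238.167	3	1926	114.621	42	3.73
29	3	3	105	3	220.167	3	2005	112.481	33	2.7
30	4	3	107	3.7	210.667	3	1838	113.732	39	3.52
31	4	4	134	4	269.333	4	2583	146.587	64	3.72
32	6	3	161	5.1	359.167	3	2613	162.401	63	4
33	12	4	211	8.7	413.333	5	5448	275.448	140	4.98
34	17	4	234	11.9	433.667	5	7138	340.369	192	5.44
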
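mirna	starred	count_na	count_da	seq_fc	seq_p	seq_fdr	array_na	array_da	array_fc	array_p	array_fdr
miR-200-3p	1	1011	3148	1.60	2.80E-239	1.10E-238	1359	6563	2.27	6.26E-05	2.08E-04
miR-2004	1	2633	7067	1.38	0	0	19984	49699	1.31	1.70E-05	6.88E-05
miR-2010	1	3564	14243	1.96	0	0	659	5803	3.14	4.73E-05	1.65E-04
miR-22	1	181	736	1.98	9.39E-77	3.05E-76	135	641	2.25	1.15E-05	5.04E-05
miR-252a	1	114	355	1.60	1.59E-28	3.87E-28	104	591	2.51	2.46E-08	2.31E-07
miR-252a-5p	1	116	357	1.58	2.91E-28	6.99E-28	103	593	2.53	6.14E-09	1.05E-07
miR-7	1	10559	29640	1.45	0	0	440	4101	3.22	2.04E-05	7.78E-05
miR-92	1	55629	142056	1.31	0	0	4758	9777	1.04	2.09E-10	4.31E-08
miR-92a	1	43473	90546	1.02	0	0	4217	8821	1.06	2.45E-09	8.41E-08
miR-153	0	58	299	2.32	5.77E-39	1.58E-38	5378	4439	-0.28	4.50E-04	1.10E-03
miR-153-3p	0	51	268	2.35	1.45E-35	3.76E-35	4662	2884	-0.68	5.65E-06	2.64E-05
miR-2008	0	405	1618	1.96	9.83E-164	3.60E-163	9953	1092	-3.19	2.92E-09	8.60E-08
miR-310	0	33	184	2.44	6.74E-26	1.52E-25	483	823	0.77	1.77E-06	9.84E-06
miR-310-3p	0	25	84	1.71	1.86E-08	2.94E-08	1670	1114	-0.58	9.99E-03	1.38E-02
miR-71a	0	153	410	1.38	1.18E-26	2.71E-26	1798	1550	-0.21	4.81E-02	5.32E-02
miR-71a-5p	0	25	84	1.71	1.86E-08	2.91E-08	8982	9585	0.09	9.73E-02	9.82E-02
miR-92c	0	41719	85216	0.9888	0	0	4241	8728	1.04	3.35E-10	3.45E-08
miR-92-3p	0	40066	81951	0.9907	0	0	4146	8610	1.05	1.15E-09	5.91E-08
miR-235a	0	6071	10122	0.6958	4.89E-200	1.80E-199	4720	9771	1.05	7.50E-08	5.72E-07
miR-7-5p	0	13133	23804	0.8163	0	0	454	4611	3.34	1.56E-05	6.57E-05
miR-2012-5p	0	475339	804653	0.7177	0	0	3150	6703	1.09	6.06E-05	2.05E-04
miR-2008	0	405	1618	1.9566	9.83E-164	3.60E-163	9953	1092	-3.19	2.92E-09	8.60E-08
let-7a-5p	0	817	1658	0.9794	3.74E-60	1.14E-59	4284	1488	-1.53	1.88E-05	7.45E-05
miR-210	0	91179	86593	-0.116	1.48E-64	4.62E-64	13777	2116	-2.70	1.34E-04	4.12E-04
miR-210-3p	0	93148	88209	-0.12	1.80E-70	5.74E-70	13782	2108	-2.71	1.41E-04	4.28E-04
let-7-5p	0	996	1456	0.5061	7.83E-18	1.63E-17	645	107	-2.59	1.77E-04	5.00E-04
miR-31a-5p	0	2181	1517	-0.565	2.97E-32	7.35E-32	11587	4989	-1.22	6.09E-04	1.38E-03
miR-2011	0	290828	305417	0.0289	9.51E-15	1.83E-14	57203	14562	-1.97	8.94E-04	1.96E-03
miR-375-3p	0	90125	119762	0.3685	0	0	613	101	-2.60	1.05E-03	2.21E-03
miR-31-5p	0	209383	168625	-0.354	0	0	11128	5180	-1.10	1.14E-03	2.36E-03
miR-72-5p	0	191131	158706	-0.31	0	0	10172	4848	-1.07	1.27E-03	2.57E-03
miR-375	0	96422	129304	0.3817	0	0	646	101	-2.68	1.91E-03	3.36E-03
miR-29a	0	2032	3541	0.7596	1.01E-82	3.35E-82	1621	342	-2.25	2.89E-03	4.76E-03
miR-375b-3p	0	68871	90878	0.3584	0	0	673	124	-2.44	3.05E-03	4.94E-03
miR-10a-5p	0	2891589	1423173	-1.06	0	0	27597	26595	-0.05	1.66E-03	3.02E-03
miR-2006	0	6401	1762	-1.90	0	0	4292	2835	-0.6	4.05E-05	1.49E-04
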
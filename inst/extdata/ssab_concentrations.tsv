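compound	sample	concentration	rsd_percent
Pyrazine	GT	82.11	4.08
Pyrazine	WZJ	192.41	2.1
Pyrazine	ZY	85.25	3.66
Pyrazine	QHZ	176.21	5.02
Pyrazine	DYT	196.79	1.45
Pyrazine	XJ	193.92	1.06
Pyrazine	LJ	71.14	0.67
Pyrazine	ZJ	117.55	2.23
Pyrazine	WL	99.8	4.11
Pyrazine	FM	73.08	3.8
Pyrazine	ZZY	29.81	4.5
2M	GT	135.21	1.17
2M	WZJ	110.54	3.64
2M	ZY	148.2	0.65
2M	QHZ	195.29	0.59
2M	DYT	159.41	1.97
2M	XJ	115.33	2.2
2M	LJ	62.15	5.41
2M	ZJ	36.02	3.41
2M	WL	71.56	3.09
2M	FM	56.88	2.16
2M	ZZY	51.06	1.97
26DM	GT	1257.48	3.24
26DM	WZJ	992.28	1.97
26DM	ZY	1497.57	3.96
26DM	QHZ	1116.28	6.09
26DM	DYT	1054.61	0.88
26DM	XJ	951.06	1.28
26DM	LJ	735.28	0.69
26DM	ZJ	1589.16	0.47
26DM	WL	878.3	2.78
26DM	FM	459.48	4.6
26DM	ZZY	618.19	1.06
TM2YM	GT	6.51	1.76
TM2YM	WZJ	74.7	2.89
TM2YM	ZY	53.07	3.37
TM2YM	QHZ	54.1	1.92
TM2YM	DYT	25.4	6.17
TM2YM	XJ	39.28	3.06
TM2YM	LJ	7.05	2.71
TM2YM	ZJ	17.33	4.32
TM2YM	WL	10.54	3.66
TM2YM	FM	18.14	2.79
TM2YM	ZZY	10.92	1.78
23DM	GT	312.01	3.96
23DM	WZJ	175.8	2.24
23DM	ZY	682.51	2.09
23DM	QHZ	290.8	1.88
23DM	DYT	195.26	3.62
23DM	XJ	315.7	3.84
23DM	LJ	112.66	0.77
23DM	ZJ	295.3	2.6
23DM	WL	237.4	4.78
23DM	FM	125.89	3.5
23DM	ZZY	167.2	0.88
2356TTM	GT	1861.98	7.09
2356TTM	WZJ	1634.52	1.02
2356TTM	ZY	805.19	0.56
2356TTM	QHZ	1208.3	1.70
2356TTM	DYT	895.22	0.79
2356TTM	XJ	1183.12	4.41
2356TTM	LJ	474.99	4.27
2356TTM	ZJ	1609.47	2.28
2356TTM	WL	601.51	4.04
2356TTM	FM	693.42	2.19
2356TTM	ZZY	886.07	4.78
235TM	GT	1086.25	0.71
235TM	WZJ	1328.06	1.37
235TM	ZY	866.33	1.05
235TM	QHZ	950.19	1.36
235TM	DYT	760.57	5.81
235TM	XJ	906.55	5.52
235TM	LJ	440.1	0.83
235TM	ZJ	1754.48	1.27
235TM	WL	497.11	3.74
235TM	FM	316.52	1.53
235TM	ZZY	513.97	4.24
2A3M	GT	236.75	3.5
2A3M	WZJ	156.34	0.57
2A3M	ZY	79.26	2.97
2A3M	QHZ	125.41	4.43
2A3M	DYT	196.22	5.09
2A3M	XJ	261.07	1.76
2A3M	LJ	78.15	1.69
2A3M	ZJ	56.12	3.56
2A3M	WL	65.4	1.86
2A3M	FM	72.3	3.71
2A3M	ZZY	49.49	3.55
2E6M	GT	428.24	2.04
2E6M	WZJ	330.72	1.45
2E6M	ZY	502.11	0.54
2E6M	QHZ	255.9	4.15
2E6M	DYT	420.85	6.20
2E6M	XJ	369.26	0.63
2E6M	LJ	361.98	6.02
2E6M	ZJ	690.69	0.57
2E6M	WL	400.24	7.64
2E6M	FM	336.76	2.3
2E6M	ZZY	293.25	5.29
2E3M	GT	8.19	0.74
2E3M	WZJ	19.33	0.62
2E3M	ZY	6.49	2.51
2E3M	QHZ	23.1	4.28
2E3M	DYT	19.84	4.2
2E3M	XJ	7.11	3.79
2E3M	LJ	6.19	2.09
2E3M	ZJ	46.19	4.92
2E3M	WL	5.1	0.79
2E3M	FM	6.71	0.33
2E3M	ZZY	2.65	2.81
2E35DM	GT	389.85	2.04
2E35DM	WZJ	294.45	2.55
2E35DM	ZY	240.44	0.76
2E35DM	QHZ	153.61	1.68
2E35DM	DYT	486.49	3.96
2E35DM	XJ	251.42	4.65
2E35DM	LJ	100.23	0.77
2E35DM	ZJ	521.57	2.14
2E35DM	WL	112.3	3.01
2E35DM	FM	83.75	4.18
2E35DM	ZZY	95.1	4.21
5E23DM	GT	1.83	4.22
5E23DM	WZJ	6.42	1.09
5E23DM	ZY	1.64	0.41
5E23DM	QHZ	2.04	1.56
5E23DM	DYT	5.68	2.8
5E23DM	XJ	12.52	4.55
5E23DM	LJ	1.01	3.09
5E23DM	ZJ	1.64	2.47
5E23DM	WL	0.83	0.85
5E23DM	FM	1.75	2.76
5E23DM	ZZY	1.23	3.09
26DE	GT	25.33	2.19
26DE	WZJ	39.57	3.44
26DE	ZY	31.09	1.09
26DE	QHZ	11.75	0.77
26DE	DYT	43.21	2.59
26DE	XJ	52.41	6.78
26DE	LJ	75.21	4.58
26DE	ZJ	17.08	3.92
26DE	WL	12	2.06
26DE	FM	17.63	3.9
26DE	ZZY	15.33	2.77
23DE	GT	159.15	3.9
23DE	WZJ	240.14	4.83
23DE	ZY	125.61	5.24
23DE	QHZ	107.55	2.88
23DE	DYT	167.61	1.89
23DE	XJ	110.9	3.06
23DE	LJ	64.8	4.71
23DE	ZJ	97.14	2.09
23DE	WL	62.4	5.11
23DE	FM	78.6	4.3
23DE	ZZY	28.08	3.11
23DE5M	GT	13.76	2.81
23DE5M	WZJ	10.54	1.97
23DE5M	ZY	15.47	3.35
23DE5M	QHZ	11.86	6.09
23DE5M	DYT	4.5	1.44
23DE5M	XJ	6.69	3.79
23DE5M	LJ	4.39	4.29
23DE5M	ZJ	2.71	3.09
23DE5M	WL	4.16	6.5
23DE5M	FM	1.7	3.72
23DE5M	ZZY	1.09	1.03
2I3M	GT	2.31	5.09
2I3M	WZJ	5.87	2.78
2I3M	ZY	4.25	1.83
2I3M	QHZ	4.25	1.09
2I3M	DYT	1.33	4.62
2I3M	XJ	1.41	3.7
2I3M	LJ	3.82	2.88
2I3M	ZJ	0.96	6.47
2I3M	WL	1.14	4.55
2I3M	FM	1.92	3.29
2I3M	ZZY	3.18	2.74
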
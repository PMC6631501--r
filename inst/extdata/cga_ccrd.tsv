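run	temperature	ethanol	ls_ratio	power	yield	yield_sd	rsm_pred_pub	ann_pred_pub
1	40	65	20	105	20.75	3.60	25.45	20.77
2	60	65	20	105	39.41	1.31	34.99	39.37
3	40	85	20	105	18.70	1.92	20.01	18.70
4	60	85	20	105	35.23	1.74	32.99	35.24
5	40	65	40	105	38.02	3.10	40.56	38.01
6	60	65	40	105	39.84	2.06	43.18	41.49
7	40	85	40	105	34.12	2.26	30.11	34.12
8	60	85	40	105	37.67	2.00	36.16	37.66
9	40	65	20	135	30.65	1.29	32.23	30.64
10	60	65	20	135	30.44	4.18	34.82	30.84
11	40	85	20	135	29.68	3.48	26.72	29.66
12	60	85	20	135	35.23	2.62	32.75	35.24
13	40	65	40	135	40.74	1.79	43.36	43.92
14	60	65	40	135	40.25	2.78	39.02	40.62
15	40	85	40	135	28.33	3.10	32.83	28.32
16	60	85	40	135	36.25	0.74	31.94	35.93
17	30	75	30	120	37.59	1.16	32.67	37.94
18	70	75	30	120	36.85	1.17	41.31	36.84
19	50	55	30	120	38.32	0.77	31.79	38.32
20	50	95	30	120	13.18	2.34	19.26	13.18
21	50	75	10	120	26.31	0.95	26.60	26.33
22	50	75	50	120	41.64	2.47	40.90	41.65
23	50	75	30	90	36.35	1.39	36.73	36.36
24	50	75	30	150	40.12	1.57	39.29	38.58
25	50	75	30	120	39.78	2.38	39.92	39.89
26	50	75	30	120	39.99	2.33	39.92	39.89
27	50	75	30	120	39.98	0.35	39.92	39.89
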
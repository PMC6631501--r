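run	temperature	ethanol	ls_ratio	power	yield	yield_sd	rsm_pred_pub	ann_pred_pub
1	60	65	30	120	39.65	0.97	40.02	39.98
2	50	75	20	135	34.45	2.17	35.96	33.29
3	60	75	30	135	37.70	3.13	39.77	36.69
4	50	65	20	120	33.70	2.55	33.08	33.82
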
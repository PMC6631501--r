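name	unit	symbol	center	step
temperature	degC	X1	50	10
ethanol	%	X2	75	10
ls_ratio	mL/g	X3	30	10
power	W	X4	120	15
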
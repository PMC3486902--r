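arm	abnormal_samples	total_samples	abnormal_proportion
carrier	.	.	0.6981
control	1185	1861	.
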
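line	replicate	FW	PH	BF
WT	1	98.4	176.2	11.8
WT	2	102.1	179.5	12.3
WT	3	95.7	178.1	11.5
ftdm	1	61.2	74.9	29.8
ftdm	2	63.8	76.4	30.6
ftdm	3	60.1	75.2	28.9
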
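compound	stock_concentration	role
26DM	1110	supra_threshold
2E6M	250	supra_threshold
235TM	950	supra_threshold
2E35DM	150	supra_threshold
23DM	290	sub_threshold
23DE	100	sub_threshold
23DE5M	11	sub_threshold
2A3M	120	sub_threshold
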
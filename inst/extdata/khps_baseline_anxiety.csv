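covariate,category,low_flat,low_to_middle,high_to_low,high_curved
sex,male,1664,26,20,4
sex,female,2121,70,69,9
economic_activity,no,2382,61,70,9
economic_activity,yes,1403,35,19,4
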
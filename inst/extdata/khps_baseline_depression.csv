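covariate,category,low_flat,low_to_middle,low_to_high,high_stable
anxiety_group,low_flat,3519,162,28,76
anxiety_group,low_to_middle,61,29,3,3
anxiety_group,high_to_low,57,7,2,23
anxiety_group,high_curved,4,7,0,2
sex,male,1619,59,9,27
sex,female,2022,146,24,77
residential_area,metro_city,1392,75,14,39
residential_area,not_metro_city,2249,130,19,65
living_arrangement,alone,59,1,0,2
living_arrangement,couple_only,2231,145,21,69
living_arrangement,others,1351,59,12,33
chronic3,yes,3175,198,32,102
chronic3,no,466,7,1,2
economic_activity,no,2278,135,27,82
economic_activity,yes,1363,70,6,22
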
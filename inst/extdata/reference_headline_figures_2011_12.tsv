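name	value
episodes_recorded	18808903
episodes_ungroupable	1659295
episodes_total	19392171
elective_episodes	11477435
emergency_episodes	7914736
observed_cost_reference_female_gbp	2608800295
observed_cost_reference_male_gbp	2208982887
observed_cost_reference_total_gbp	4817783181
annual_cost_per_resident_most_deprived_gbp	597
annual_cost_per_resident_least_deprived_gbp	455
lifetime_cost_male_least_deprived_gbp	43358
lifetime_cost_male_most_deprived_gbp	50163
lifetime_cost_female_least_deprived_gbp	48409
lifetime_cost_female_most_deprived_gbp	59255
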
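quintile	elective_n	elective_rate	emergency_n	emergency_rate	all_n	all_rate
Q1	2481014	23727	2055481	19658	4536495	43385
Q2	2355297	22338	1706833	16188	4062130	38526
Q3	2310208	21811	1546013	14596	3856220	36408
Q4	2235779	21254	1390347	13217	3626126	34472
Q5	2095137	19804	1216063	11495	3311200	31298
Overall	11477435	21783	7914736	15021	19392171	36804
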
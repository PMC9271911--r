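study_id,year,ethnicity,control_type,matching,n_cases,n_controls,case_ref_hom,case_het,case_eff_hom,control_ref_hom,control_het,control_eff_hom,nos_score
b60,,asian,healthy,age_and_sex,301,233,250,48,3,194,35,4,7
b68,,mixed,healthy,age_and_sex,66,102,34,28,4,38,52,12,7
b10,,mixed,healthy,age_and_sex,170,103,77,78,15,38,53,12,7
b18,,african,healthy,age_and_sex,917,748,485,354,66,436,264,36,7
b32,,asian,non_diabetic,age_and_sex,36,170,26,10,0,145,25,0,6
b4,,asian,non_diabetic,age_and_sex,89,299,63,24,2,250,49,0,8
b69,,mixed,healthy,age_and_sex,617,100,233,264,120,42,46,12,9
b41,,asian,healthy,age_and_sex,1234,1272,916,268,20,960,264,16,7
b25,,indian,healthy,age_and_sex,145,100,80,50,15,84,14,2,8
b52,,caucasian,healthy,age_and_sex,200,100,48,152,0,33,67,0,6
b1,,caucasian,healthy,age_and_sex,103,100,45,45,13,41,42,17,6
b64_1,,indian,healthy,age_and_sex,461,315,273,177,11,220,90,5,8
b64_2,,indian,healthy,age_and_sex,337,200,210,116,11,145,50,5,8
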
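study_id,year,ethnicity,control_type,matching,n_cases,n_controls,case_ref_hom,case_het,case_eff_hom,control_ref_hom,control_het,control_eff_hom,nos_score
b95,,asian,healthy,age_and_sex,71,248,0,13,58,0,47,201,8
b62,,caucasian,non_diabetic,not_reported,251,110,11,85,155,5,26,79,9
b57,,asian,healthy,age_and_sex,215,155,7,36,172,0,22,133,7
b38,,asian,healthy,age_and_sex,143,85,0,40,103,1,22,62,8
b3,,asian,non_diabetic,age_and_sex,295,189,3,67,225,0,26,163,7
b27,,asian,non_diabetic,age_and_sex,85,68,3,16,66,0,7,61,7
b44,,asian,healthy,not_reported,127,70,1,14,112,0,6,64,4
b34,,caucasian,healthy,age_and_sex,410,330,34,124,252,4,74,252,8
b37,,asian,healthy,age_and_sex,800,398,14,112,674,1,57,340,8
b45,,asian,healthy,age_only,84,37,35,6,43,2,1,34,6
b92,,asian,healthy,age_and_sex,132,80,2,19,111,0,12,68,8
b47,,asian,healthy,age_and_sex,299,100,3,64,232,0,18,82,8
b73,,asian,healthy,age_and_sex,399,113,6,22,311,2,18,93,8
b14,,asian,healthy,age_and_sex,134,85,0,38,96,0,22,62,6
b91,,asian,healthy,age_and_sex,322,166,2,42,278,1,20,145,8
b83,,asian,healthy,age_and_sex,204,100,0,49,155,0,13,87,9
b68,,mixed,healthy,age_and_sex,66,102,2,16,48,4,19,79,7
b10,,mixed,healthy,age_and_sex,170,103,5,43,122,4,20,79,7
b87,,asian,healthy,age_and_sex,80,119,0,13,67,0,23,86,9
b18,,african,healthy,age_and_sex,917,748,50,305,548,20,217,511,7
b21,,caucasian,healthy,not_reported,108,160,5,29,74,1,39,120,5
b33,,caucasian,non_diabetic,not_reported,348,813,12,107,229,32,228,553,5
b11,,asian,healthy,age_and_sex,108,100,3,19,86,9,16,75,7
b89,,asian,non_diabetic,not_reported,76,100,2,10,64,1,12,87,6
b32,,asian,non_diabetic,age_and_sex,36,170,0,12,24,0,26,144,6
b4,,asian,non_diabetic,age_and_sex,89,299,2,26,61,0,51,248,8
b42,,asian,non_diabetic,age_and_sex,166,85,12,24,130,3,14,68,8
b51,,caucasian,healthy,age_and_sex,220,96,9,54,157,0,16,80,9
b69,,mixed,healthy,age_and_sex,617,100,16,158,405,3,30,67,9
b23,,asian,healthy,age_and_sex,144,63,9,7,126,2,1,60,6
b63,,caucasian,healthy,age_only,173,101,3,46,124,0,28,73,8
b70,,asian,non_diabetic,age_and_sex,278,223,1,60,217,1,24,198,8
b88,,caucasian,non_diabetic,age_and_sex,85,282,2,12,71,11,115,156,8
b1,,caucasian,healthy,age_and_sex,103,100,3,31,69,3,27,70,6
b64_1,,indian,healthy,age_and_sex,461,315,17,137,307,6,95,214,8
b64_2,,indian,healthy,age_and_sex,337,200,12,110,215,5,30,145,7
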
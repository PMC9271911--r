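study_id,year,ethnicity,control_type,matching,n_cases,n_controls,case_ref_hom,case_het,case_eff_hom,control_ref_hom,control_het,control_eff_hom,nos_score
b62,,caucasian,non_diabetic,not_reported,251,110,136,97,18,54,45,11,9
b74,,asian,healthy,age_and_sex,48,270,38,8,2,250,18,2,7
b79,,caucasian,healthy,age_and_sex,216,222,106,93,17,112,92,18,7
b38,,asian,healthy,age_and_sex,143,85,93,49,1,63,21,1,8
b60,,asian,healthy,age_and_sex,301,233,256,42,3,196,35,2,7
b58,,asian,healthy,age_and_sex,72,304,49,23,0,251,53,0,7
b55,,caucasian,healthy,not_reported,159,207,52,63,44,86,82,29,6
b56,,asian,healthy,age_and_sex,71,248,38,8,2,250,18,2,7
b65,,asian,healthy,age_and_sex,211,83,159,28,3,67,15,0,8
b71,,asian,non_diabetic,age_and_sex,177,129,147,30,0,116,13,0,9
b14,,asian,healthy,age_and_sex,134,85,88,45,1,63,21,1,6
b68,,mixed,healthy,age_and_sex,66,102,34,28,4,53,45,4,7
b10,,mixed,healthy,age_and_sex,170,103,82,78,10,54,45,4,7
b94,,asian,healthy,age_and_sex,136,61,95,41,0,49,12,0,5
b46,,asian,healthy,age_and_sex,80,119,63,17,0,98,19,2,9
b20,,asian,healthy,age_and_sex,139,63,97,42,0,51,12,0,8
b48,,asian,healthy,age_and_sex,299,100,240,59,0,86,14,0,8
b18,,african,healthy,age_and_sex,917,748,350,442,122,335,334,69,7
b66,,caucasian,non_diabetic,age_and_sex,84,84,37,47,0,38,46,0,8
b76,,asian,healthy,age_and_sex,39,100,7,31,1,72,26,2,7
b59,,caucasian,non_diabetic,age_and_sex,403,799,222,153,28,407,322,70,9
b75,,caucasian,healthy,sex_only,209,384,87,92,30,201,161,22,6
b11,,asian,healthy,age_and_sex,108,100,83,20,5,80,14,6,7
b32,,asian,non_diabetic,age_and_sex,36,170,33,3,0,135,35,0,6
b8,,caucasian,healthy,age_and_sex,97,102,46,46,5,48,42,12,8
b4,,asian,non_diabetic,age_and_sex,89,299,75,14,0,245,53,1,8
b17,,caucasian,healthy,age_and_sex,80,20,27,37,16,12,7,1,7
b2,,indian,non_diabetic,age_and_sex,100,160,25,55,20,113,47,0,7
b69,,mixed,healthy,age_and_sex,617,100,294,261,54,47,48,5,9
b43,,asian,healthy,age_and_sex,326,215,258,67,1,171,33,1,8
b26,,asian,healthy,age_and_sex,100,50,12,63,25,12,25,13,6
b9,,asian,healthy,age_and_sex,120,60,75,45,0,43,17,0,6
b6_1,,caucasian,non_diabetic,age_and_sex,980,9657,450,426,104,4506,4181,970,8
b6_2,,african,non_diabetic,age_and_sex,728,3009,580,139,9,2338,626,45,8
b29,,indian,healthy,age_and_sex,196,190,109,88,0,162,28,0,7
b49,,caucasian,non_diabetic,age_and_sex,80,40,31,32,17,19,16,5,7
b41,,asian,healthy,age_and_sex,1234,1272,1024,189,3,978,257,9,7
b54,,caucasian,non_diabetic,age_and_sex,94,94,3,33,58,10,22,62,6
b52,,caucasian,healthy,age_and_sex,200,100,122,64,14,46,52,2,6
b67,,indian,healthy,age_and_sex,200,200,133,57,10,132,54,14,6
b1,,caucasian,healthy,age_and_sex,103,100,59,35,9,49,40,11,6
b64_1,,indian,healthy,age_and_sex,461,315,289,159,13,214,96,5,8
b64_2,,indian,healthy,age_and_sex,337,200,192,133,12,137,58,5,8
b24,,caucasian,non_diabetic,age_and_sex,111,164,63,39,9,107,51,6,8
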
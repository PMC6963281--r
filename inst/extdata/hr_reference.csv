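kind,name,age_40_50,age_50_60,age_60_70,age_70_80,age_80_90
mean,stage_I,72.6,69.2,70.1,68.70,67.20
mean,stage_II,74.6,72.3,71.3,70.3,69.3
mean,stage_III,77.5,75.2,74.2,73.6,72.6
mean,stage_IV,84.9,82.2,81.2,80.2,79.2
sd,stage_I,12,11,8,7,9
sd,stage_II,13,12,11,10,12
sd,stage_III,13,12,11,11,10
sd,stage_IV,14,13,12,10,11
modifier,smoker,6.6,,,,
modifier,obese,9,,,,
modifier,inhaler,7,,,,
modifier,CHF,9.6,,,,
modifier,anemia,7,,,,
modifier,PH,10,,,,
modifier,asthma,8,,,,
modifier,female_offset,3,,,,
exercise_mean,sedentary,76.3,,,,
exercise_mean,light,85.5,,,,
exercise_mean,moderate,125.6,,,,
exercise_mean,vigorous,145.3,,,,
exercise_sd,sedentary,10,,,,
exercise_sd,light,15,,,,
exercise_sd,moderate,18,,,,
exercise_sd,vigorous,25,,,,
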
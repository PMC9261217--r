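task,text,expected_label
diet,Pt is having fatty food,high_fat_diet
diet,He had token high calorie diet for 2 weeks,high_calorie_diet
diet,His current diet contains too much food with high salt,high_salt_diet
diet,She backs to normal diet,normal_diet
diet,She has no knowledge of salt restrictions,nonspecific_abnormal
activity,Pt has increase regular physical activity,physical_activity
activity,He didn't maintain daily exercise,physical_inactivity
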
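task: diet
window_size: 5
class_keywords:
  high_calorie_diet:
    - "high calorie diet"
  high_fat_diet:
    - "high fat diet"
    - "fatty food"
  high_salt_diet:
    - "high salt diet"
    - "high salt"
  normal_diet:
    - "normal"
    - "normal diet"
    - "salt restrictions"
negation_terms:
  - "no"
  - "not"
  - "never"
  - "without"
  - "denies"
  - "denied"
  - "didnt"
  - "dont"
  - "doesnt"
  - "cant"
  - "wont"
  - "isnt"
  - "wasnt"
  - "neither"
  - "nor"
  - "none"
prospective_triggers:
  - "can"
  - "resume"
  - "begin"
  - "start"
  - "going"
  - "may"
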
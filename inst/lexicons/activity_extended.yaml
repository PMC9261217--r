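task: activity
window_size: 5
class_keywords:
  physical_activity:
    - "active"
    - "activity"
    - "exercise"
    - "exercises"
    - "exercising"
    - "physical activity"
  physical_inactivity:
    - "inactive"
    - "inactivity"
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
prospective_triggers: []
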
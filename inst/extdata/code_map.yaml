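charlson:
- name: myocardial_infarction
  prefixes:
  - I21
  - I22
  - I252
  weight: 1
- name: heart_failure
  prefixes:
  - I50
  weight: 1
- name: peripheral_vascular
  prefixes:
  - I70
  - I71
  - I731
  weight: 1
- name: cerebrovascular
  prefixes:
  - I60
  - I61
  - I63
  - I64
  - G45
  weight: 1
- name: dementia
  prefixes:
  - F00
  - F01
  - F03
  - G30
  weight: 1
- name: chronic_pulmonary
  prefixes:
  - J40
  - J41
  - J42
  - J43
  - J44
  - J45
  - J47
  weight: 1
- name: rheumatic
  prefixes:
  - M05
  - M06
  - M32
  - M33
  - M34
  weight: 1
- name: peptic_ulcer
  prefixes:
  - K25
  - K26
  - K28
  weight: 1
- name: mild_liver
  prefixes:
  - K70
  - K73
  - K74
  weight: 1
- name: diabetes
  prefixes:
  - E100
  - E110
  - E119
  - E140
  weight: 1
- name: diabetes_complications
  prefixes:
  - E102
  - E112
  - E142
  weight: 2
- name: hemiplegia
  prefixes:
  - G81
  - G82
  weight: 2
- name: renal
  prefixes:
  - N18
  - N19
  - N052
  weight: 2
- name: malignancy
  prefixes:
  - C0
  - C1
  - C2
  - C3
  - C4
  - C6
  weight: 2
- name: severe_liver
  prefixes:
  - K721
  - K729
  - I85
  weight: 3
- name: metastatic_cancer
  prefixes:
  - C77
  - C78
  - C79
  weight: 6
- name: aids
  prefixes:
  - B20
  - B21
  - B22
  - B24
  weight: 6
frailty:
- name: activity_limitation
  prefixes:
  - Z74
- name: anaemia
  prefixes:
  - D64
- name: arthritis
  prefixes:
  - M19
- name: cerebrovascular_seq
  prefixes:
  - I69
- name: cognitive_impairment
  prefixes:
  - F06
- name: delirium
  prefixes:
  - F05
- name: syncope
  prefixes:
  - R55
- name: care_dependence
  prefixes:
  - Z75
- name: depression
  prefixes:
  - F32
- name: diabetes_frailty
  prefixes:
  - E11
- name: dizziness
  prefixes:
  - R42
- name: falls
  prefixes:
  - W19
- name: foot_problems
  prefixes:
  - L97
- name: fragility_fracture
  prefixes:
  - S72
- name: hearing_impairment
  prefixes:
  - H91
- name: chronic_pain
  prefixes:
  - R52
- name: hypotension
  prefixes:
  - I95
- name: urinary_incontinence
  prefixes:
  - R32
- name: faecal_incontinence
  prefixes:
  - R15
- name: malnutrition
  prefixes:
  - E46
- name: memory_loss
  prefixes:
  - R41
- name: mobility_problems
  prefixes:
  - R26
- name: osteoporosis
  prefixes:
  - M81
- name: parkinsonism
  prefixes:
  - G20
- name: peptic_ulcer_frailty
  prefixes:
  - K27
- name: pressure_ulcer
  prefixes:
  - L89
- name: respiratory_failure
  prefixes:
  - J96
- name: self_care_difficulty
  prefixes:
  - Z73
- name: senility
  prefixes:
  - R54
- name: sleep_disorder
  prefixes:
  - G47
- name: visual_impairment
  prefixes:
  - H54
- name: weight_loss
  prefixes:
  - R63
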
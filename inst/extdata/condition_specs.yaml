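appendicitis:
  name: appendicitis
  include_codes:
  - K35
  - K36
  - K37
  es_procedure_codes:
  - H01
  - H02
  - H03
  es_window_days: 7.0
  strict_es_procedure_codes:
  - H01
  - H02
  strict_window_days: 7.0
  lookback_exclusion_days: 365
gallstone_disease:
  name: gallstone_disease
  include_codes:
  - K80
  es_procedure_codes:
  - J18
  - J21
  es_window_days: 7.0
  strict_es_procedure_codes:
  - J18
  strict_window_days: 7.0
  lookback_exclusion_days: 365
diverticular_disease:
  name: diverticular_disease
  include_codes:
  - K57
  es_procedure_codes:
  - H33
  - H15
  - T46
  es_window_days: any_time
  strict_es_procedure_codes:
  - H33
  - H15
  strict_window_days: any_time
  lookback_exclusion_days: 365
hernia:
  name: hernia
  include_codes:
  - K40
  - K41
  - K42
  - K43
  - K45
  - K46
  es_procedure_codes:
  - T19
  - T20
  - T21
  - T22
  - T23
  - T24
  - T25
  - T26
  - T27
  es_window_days: 3.0
  strict_es_procedure_codes:
  - T19
  - T20
  - T21
  - T22
  strict_window_days: 3.0
  lookback_exclusion_days: 365
intestinal_obstruction:
  name: intestinal_obstruction
  include_codes:
  - K56
  es_procedure_codes:
  - G69
  - H07
  - H29
  - T41
  es_window_days: 7.0
  strict_es_procedure_codes:
  - G69
  - H07
  strict_window_days: 7.0
  lookback_exclusion_days: 365
  second_field_rule:
    main_prefixes:
    - C18
    - C19
    - C20
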
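cohort_size: 10000.0
screening:
  combined:
    '150':
      detection_rate: 0.85
      false_positive_rate: 0.025
    '500':
      detection_rate: 0.94
      false_positive_rate: 0.07
    '1000':
      detection_rate: 0.96
      false_positive_rate: 0.12
    '2000':
      detection_rate: 0.98
      false_positive_rate: 0.19
  quadruple:
    detection_rate: 0.805
    false_positive_rate: 0.04
  nt_failure:
    first_week: 11.0
    last_week: 14.0
    first_rate: 0.14
    last_rate: 0.19
invasive:
  cvs:
    detection_rate: 1.0
    sample_failure_rate: 0.013
    procedure_miscarriage_rate: 0.005
  amniocentesis:
    detection_rate: 1.0
    sample_failure_rate: 0.008
    procedure_miscarriage_rate: 0.005
nipt:
  detection_rate: 0.99
  false_positive_rate: 0.01
  sample_failure_rate: 0.05
  procedure_miscarriage_rate: 0.0
loss_rates:
  unaffected:
    weeks_10_25: 0.0012
    weeks_26_40: 0.00034
  affected:
    weeks_10_15: 0.07067
    weeks_16_40: 0.0051
uptakes:
  screening: 0.69
  late_arrival: 0.15
  invasive_unaffected: 0.8
  invasive_affected: 0.9
  nipt_unaffected: 0.8
  nipt_affected: 0.9
  nipt_firstline: 0.69
  top: 0.921
birth_mode:
  vaginal: 0.752
  caesarean: 0.248
costs:
  combined_test: 27.0
  quadruple_test: 35.0
  invasive_test: 479.0
  fetal_loss: 511.0
  top_first_trimester: 697.0
  top_second_trimester: 882.0
  vaginal_birth: 1341.0
  caesarean_birth: 2436.0
  nipt_test: 500.0
  blood_draw: 3.0
  repeat_nt: 6.5
timing:
  combined_screen: 12.0
  cvs: 13.0
  quadruple_screen: 16.0
  amniocentesis: 17.0
  contingent_nipt_t1: 13.0
  contingent_invasive_t1: 14.0
  contingent_nipt_t2: 17.0
  contingent_invasive_t2: 18.0
  firstline_nipt: 11.0
  firstline_invasive: 12.0
  first_trimester_max_week: 14.0
prevalence:
  week10_cohort_prevalence: 0.00295
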
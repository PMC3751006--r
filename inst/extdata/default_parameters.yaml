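settings:
  discount_rate: 0.03
  horizon: 40
  cycle_length: 1
  cohort_size: 20000
  tunnel_length: 6
  fx_rate: 7.69479999999999986
  age_ratio:
    '25': 1.0
    '40': 2.60000000000000009
    '60': 8.0
  post_tunnel_rate: control
  screen_alone_uses_column_rates: no
  cost_population: subgroup
  eligibility: baseline_plus_incident
  range_type: percentile
screening:
  neg_rate_2hpg: 0.95999999999999996
  ogtt_positive_rate: 0.30499999999999999
  igt_fraction_of_positive: 0.47799999999999998
  detection_level: 1.0
  compliance: 1.0
shared:
  normal_to_igt: 0.0128
  igt_to_normal: 0.11600000000000001
strategies:
  diet:
    id: diet
    igt_to_dm:
      '25': 0.029
      '40': 0.07539999999999999
      '60': 0.23200000000000001
    complication_incidence:
      cvd: 0.062
      nephropathy: 0.001
      neuropathy: 0.0043
      retinopathy: 0.0046
    complication_mortality:
      cvd: 0.0058
      nephropathy: 0.0008
    annual_intervention_cost: 362.0
    has_screening: yes
  exercise:
    id: exercise
    igt_to_dm:
      '25': 0.0273
      '40': 0.07099999999999999
      '60': 0.21840000000000001
    complication_incidence:
      cvd: 0.062
      nephropathy: 0.001
      neuropathy: 0.0043
      retinopathy: 0.0046
    complication_mortality:
      cvd: 0.0058
      nephropathy: 0.0008
    annual_intervention_cost: 362.0
    has_screening: yes
  duo:
    id: duo
    igt_to_dm:
      '25': 0.0275
      '40': 0.0716
      '60': 0.22
    complication_incidence:
      cvd: 0.062
      nephropathy: 0.001
      neuropathy: 0.0043
      retinopathy: 0.0046
    complication_mortality:
      cvd: 0.0058
      nephropathy: 0.0008
    annual_intervention_cost: 371.0
    has_screening: yes
  screen_only:
    id: screen_only
    igt_to_dm:
      '25': 0.04
      '40': 0.104
      '60': 0.35999999999999999
    complication_incidence:
      cvd: 0.0675
      nephropathy: 0.001
      neuropathy: 0.005
      retinopathy: 0.0081
    complication_mortality:
      cvd: 0.0087
      nephropathy: 0.0003
    annual_intervention_cost: 0.0
    has_screening: yes
  control:
    id: control
    igt_to_dm:
      '25': 0.0644
      '40': 0.16700000000000001
      '60': 0.57779999999999998
    complication_incidence:
      cvd: 0.0675
      nephropathy: 0.001
      neuropathy: 0.005
      retinopathy: 0.0081
    complication_mortality:
      cvd: 0.0087
      nephropathy: 0.0003
    annual_intervention_cost: 0.0
    has_screening: no
costs:
  onset_dm: 897.0
  cvd: 2078.0
  nephropathy: 1089.0
  neuropathy: 1324.0
  retinopathy: 888.0
  screening: 3.0
utilities:
  table:
    normal:
      '25': 1.0
      '40': 1.0
      '60': 1.0
    igt:
      '25': 0.94999999999999996
      '40': 0.94999999999999996
      '60': 0.94999999999999996
    onset_dm:
      '25': 0.80500000000000005
      '40': 0.80000000000000004
      '60': 0.79400000000000004
    cvd:
      '25': 0.67900000000000005
      '40': 0.67400000000000004
      '60': 0.58399999999999996
    retinopathy:
      '25': 0.70499999999999996
      '40': 0.69999999999999996
      '60': 0.60999999999999999
    nephropathy:
      '25': 0.64600000000000002
      '40': 0.64100000000000001
      '60': 0.55100000000000005
    neuropathy:
      '25': 0.66700000000000004
      '40': 0.66200000000000003
      '60': 0.57199999999999995
    death:
      '25': 0.0
      '40': 0.0
      '60': 0.0
  age_coefficient: -0.0003
  comorbidity_coefficient: 0.08400000000000001
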
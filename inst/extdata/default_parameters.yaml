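# Default model parameters (2021 euros). Each uncertain entry carries its
# PSA distribution family, the mean and SE used for sampling, and the
# published interval where one exists (se_rule notes how the SE was
# obtained: from the CI via (upper-lower)/(2*1.96), or from +/-25% bounds).
meta:
  currency: EUR-2021
  version: 1
clinical:
  hr_lifestyle:
    value: 0.74
    ci: [0.53, 1.03]
    family: lognormal
    se: 0.17
    se_rule: printed
  hr_combined:
    value: 0.51
    ci: [0.37, 0.69]
    family: lognormal
    se: 0.10
    se_rule: printed
  hr_mortality_t2d_female:
    value: 2.47
    ci: [2.23, 2.72]
    family: lognormal
    se: 0.12
    se_rule: ci
  hr_mortality_t2d_male:
    value: 1.93
    ci: [1.79, 2.07]
    family: lognormal
    se: 0.07
    se_rule: ci
  hr_mortality_complications:
    value: 2.36
    ci: [1.70, 3.29]
    family: lognormal
    se: 0.34
    se_rule: printed
policy:
  risk_threshold: 0.20
  effect_duration_years: 15
  medical_uptake: 0.30
  adherence: 1.0
  medical_cost_years: 1
  complications_hr_on_top: false
costs:
  productivity_t2d:
    value: 7632
    ci: [5724, 9540]
    family: gamma
    se: 974
    se_rule: pm25
    note: applies while aged under 65 only
  complications_extra:
    value: 4401
    ci: [3301, 5501]
    family: gamma
    se: 561
    se_rule: ci
  t2d_secondary_care:
    value: 3315
    ci: [2486, 4144]
    family: gamma
    se: 423
    se_rule: ci
  medical_therapy_annual:
    value: 1965
    family: fixed
  lifestyle_intervention:
    value: 650
    ci: [488, 813]
    family: gamma
    se: 83
    se_rule: pm25
    note: one-off cost in year 1
  prs_test:
    value: 50
    family: fixed
  t2d_primary_care_male:
    value: 562
    family: gamma
    se: 9.53
  t2d_primary_care_female:
    value: 542
    family: gamma
    se: 9.82
  t2d_medication:
    value: 584
    ci: [438, 730]
    family: gamma
    se: 74
    se_rule: pm25
utilities:
  baseline:
    female:
      "30-44": {value: 0.906, se: 0.003, family: beta}
      "45-54": {value: 0.865, se: 0.005, family: beta}
      "55-64": {value: 0.810, se: 0.006, family: beta}
      "65+":   {value: 0.770, se: 0.008, family: beta}
    male:
      "30-44": {value: 0.917, se: 0.003, family: beta}
      "45-54": {value: 0.876, se: 0.005, family: beta}
      "55-64": {value: 0.821, se: 0.006, family: beta}
      "65+":   {value: 0.781, se: 0.008, family: beta}
  disutility_t2d:
    value: 0.041
    se: 0.012
    family: beta
  disutility_complications:
    value: 0.119
    ci: [0.078, 0.160]
    family: beta
    shape1: 55.45
    shape2: 410.50
discount:
  rate: 0.03
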
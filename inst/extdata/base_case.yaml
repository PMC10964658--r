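meta:
  currency_year: 2020.0
  inflation_factor: 1.0
discount:
  cost_rate: 0.04
  effect_rate: 0.015
cohort:
  start_age: 73.0
  fraction_female: 0.35
  horizon_years: 50.0
  cycle_length_months: 1.0
life_table:
  makeham_a: 0.041894352432973
  gompertz_b: 6.690044589883318e-09
  gompertz_c: 2.705589684747123
  female_hazard_factor: 0.55
  min_age: 55.0
  terminal_age: 110.0
  anchor_age: 73.0
acute:
  tavi:
    death: 0.004
    disabling_stroke: 0.002
    new_treated_af: 0.05
    pacemaker_implant: 0.065
    myocardial_infarction: 0.01
    rehospitalization: 0.07
  savr:
    death: 0.011
    disabling_stroke: 0.008
    new_treated_af: 0.32
    pacemaker_implant: 0.04
    myocardial_infarction: 0.008
    rehospitalization: 0.105
transitions:
  tavi:
    aw_to_af:
      year1: 0.001
      year2: 0.0008
      thereafter: 0.0008
    aw_to_ds:
      year1: 0.00012
      year2: 0.00012
      thereafter: 0.00012
    af_to_ds:
      year1: 0.0004
      year2: 0.0004
      thereafter: 0.0004
    rehospitalization:
      year1: 0.0059
      year2: 0.002
      thereafter: 0.003308359477226
    reintervention:
      early: 0.00038
      ramp_start_year: 5.0
      year22: 0.003882263889045
    rr_aw: 1.0
    rr_af: 1.656724455699087
    rr_ds: 2.2
  savr:
    aw_to_af:
      year1: 0.0015
      year2: 0.0008
      thereafter: 0.0008
    aw_to_ds:
      year1: 0.00012
      year2: 0.00012
      thereafter: 0.00012
    af_to_ds:
      year1: 0.0004
      year2: 0.0004
      thereafter: 0.0004
    rehospitalization:
      year1: 0.0088
      year2: 0.002
      thereafter: 0.001931078114491
    reintervention:
      early: 0.00038
      ramp_start_year: 5.0
      year22: 0.003882263889045
    rr_aw: 1.0
    rr_af: 1.656724455699087
    rr_ds: 2.2
costs:
  procedure:
    tavi: 35342.0
    savr: 27902.0
  acute_addon:
    tavi: 848.0
    savr: 1238.0
  reintervention: 35342.0
  af_month1: 108.0
  af_monthly: 85.0
  ds_month1: 15784.0
  ds_monthly: 699.0
  ds_caregiver_month1: 244.0
  ds_caregiver_monthly: 376.0
  aw_year1: 24.0
  aw_annual: 8.0
  pacemaker_monthly: 37.0
  rehospitalization_event: 2600.0
  mi_event: 11000.0
  death: 0.0
utilities:
  norms:
    anchor_age: 73.0
    male_u0: 0.901575022669429
    female_u0: 0.881575022669429
    slope_per_year: 0.0045
  disutility_af: 0.133745495382495
  disutility_ds: 0.28
pacemaker:
  baseline_fraction:
    tavi: 0.0
    savr: 0.0
survival_model:
  enabled: no
  family: exponential
  pars:
    rate: 0.041894358069335
  hr:
    tavi: 0.75
    savr: 1.0

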
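cohort:
  'n': 72190
  p_male: 0.487
  age_location: 50.600000000000001
  age_spread: 13.300000000000001
  age_bounds:
  - 20.0
  - 85.0
  class_proportions:
    Low: 0.35
    Mod: 0.516
    High: 0.08
    VeryHigh: 0.054
  risk_breaks:
  - 0.0
  - 0.01
  - 0.05
  - 0.1
  - 0.25
  hstni_log_mean:
    female: 0.78845736036427
    male: 1.163150809805681
  hstni_log_sd:
    female: 0.6
    male: 0.6
  risk_tni_dependence: 0.3
thresholds:
  score_cuts:
  - 0.01
  - 0.05
  - 0.1
  tni_low:
    female: 4.0
    male: 6.0
  tni_high:
    female: 10.0
    male: 12.0
policy:
  score:
    Low: 0.0
    Mod: 0.0
    High: 0.5
    VeryHigh: 1.0
  sscore:
    Low-: 0.0
    Low+: 0.01
    Low++: 0.3
    Mod-: 0.0
    Mod+: 0.75
    Mod++: 0.99
    High-: 0.3
    High+: 0.75
    High++: 0.99
    VeryHigh-: 0.99
    VeryHigh+: 1.0
events:
  p10:
    chd:
      female: 0.024
      male: 0.066
    stroke:
      female: 0.008
      male: 0.014
    death_other:
      female: 0.036
      male: 0.059
  shape:
    chd:
      female: 1.0
      male: 1.0
    stroke:
      female: 1.0
      male: 1.0
    death_other:
      female: 1.0
      male: 1.0
  calib_horizon: 10.0
  fatality:
    chd:
      female: 0.327
      male: 0.28
    stroke:
      female: 0.108
      male: 0.103
  post_event:
    horizon: 5.0
    shape: 1.0
    p:
      chd:
        <55:
          female: 0.116
          male: 0.094
        55-74:
          female: 0.3
          male: 0.29
        75+:
          female: 0.609
          male: 0.632
      stroke:
        <55:
          female: 0.12
          male: 0.147
        55-74:
          female: 0.353
          male: 0.376
        75+:
          female: 0.611
          male: 0.682
  rr_treatment: 0.65
  horizon_years: 10.0
  exact_probability_ratio: no
utilities:
  asymptomatic: 0.96
  acute_decrement_chd: 0.15
  acute_decrement_stroke: 0.19
  post_chd: 0.82
  post_stroke: 0.52
  treatment_annual_decrement: 0.01
  acute_decrement_if_fatal: no
  stop_treatment_at_event: yes
costs:
  screening: 44.0
  hstni_increment: 25.0
  prevention_annual: 595.0
  chd_year1: 15805.0
  chd_year2: 2318.0
  chd_later_annual: 600.0
  stroke_year1: 21724.0
  stroke_year2: 13528.0
  stroke_later_annual: 8571.0
  cost_cv: 0.1
  fatal_full_year1: yes
  prevention_to_death: no
discount:
  annual_rate: 0.03
experiment:
  mode: basecase
  n_runs: 100
  n_per_run: 20000
  horizon: 10.0
  wtp: 50000.0
  seed: 1
  coupling: comonotonic
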
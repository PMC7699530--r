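parameters:
- name: p_early_distant
  mean: 0.018
  low: 0.016
  high: 0.019
  family: beta
  unit: probability
  label: Early stage to distant recurrence (annual)
- name: p_early_local
  mean: 0.007
  low: 0.006
  high: 0.007
  family: beta
  unit: probability
  label: Early stage to local recurrence (annual)
- name: p_local_distant
  mean: 0.0997
  low: 0.0897
  high: 0.1097
  family: beta
  unit: probability
  label: Local recurrence to distant (annual)
- name: p_death_distant
  mean: 0.23
  low: 0.207
  high: 0.253
  family: beta
  unit: probability
  label: Death from distant recurrence (annual)
- name: p_death_local
  mean: 0.069
  low: 0.0621
  high: 0.0759
  family: beta
  unit: probability
  label: Death from local recurrence (annual)
- name: p_nonbrc_death_exercise
  mean: 0.0006
  low: 0.0
  high: 0.0032
  family: beta
  unit: probability
  label: Non-breast-cancer mortality, exercise arm (trial)
- name: p_nonbrc_death_usual
  mean: 0.0047
  low: 0.0015
  high: 0.011
  family: beta
  unit: probability
  label: Non-breast-cancer mortality, usual care (trial)
- name: p_brc_death_exercise
  mean: 0.0059
  low: 0.0028
  high: 0.0109
  family: beta
  unit: probability
  label: Breast-cancer mortality, exercise arm (trial)
- name: p_brc_death_usual
  mean: 0.0096
  low: 0.0046
  high: 0.0176
  family: beta
  unit: probability
  label: Breast-cancer mortality, usual care (trial)
- name: p_recurrence_exercise
  mean: 0.0072
  low: 0.0037
  high: 0.0125
  family: beta
  unit: probability
  label: Breast-cancer recurrence, exercise arm (trial)
- name: p_recurrence_usual
  mean: 0.0076
  low: 0.0033
  high: 0.015
  family: beta
  unit: probability
  label: Breast-cancer recurrence, usual care (trial)
- name: cost_intervention
  mean: 1344.0
  low: 1209.0
  high: 1478.0
  family: gamma
  unit: AU$
  label: Exercise intervention (one-off)
- name: cost_local_recurrence
  mean: 8679.0
  low: 7811.0
  high: 9547.0
  family: gamma
  unit: AU$
  label: Treatment of local recurrence
- name: cost_distant_recurrence
  mean: 27677.0
  low: 24900.0
  high: 30434.0
  family: gamma
  unit: AU$
  label: Treatment of distant recurrence
- name: cost_eol_brc
  mean: 25475.0
  low: 22928.0
  high: 28023.0
  family: gamma
  unit: AU$
  label: End-of-life care, breast-cancer death
- name: cost_eol_other
  mean: 12122.0
  low: 10910.0
  high: 13334.0
  family: gamma
  unit: AU$
  label: End-of-life care, other-cause death
- name: cost_oop_annual
  mean: 2538.0
  low: 797.0
  high: 9079.0
  family: lognormal
  unit: AU$
  label: Out-of-pocket expenses (annual, first 2 years)
- name: prod_premature_death
  mean: 149909.0
  low: 134918.0
  high: 164900.0
  family: gamma
  unit: AU$
  label: Productivity loss, premature breast-cancer death (<65)
- name: prod_distant
  mean: 34719.0
  low: 31248.0
  high: 38191.0
  family: gamma
  unit: AU$
  label: Productivity loss, distant recurrence
- name: prod_local
  mean: 22785.0
  low: 20506.0
  high: 25063.0
  family: gamma
  unit: AU$
  label: Productivity loss, local recurrence
- name: prod_early
  mean: 10850.0
  low: 9765.0
  high: 11935.0
  family: gamma
  unit: AU$
  label: Productivity loss, early stage (annual)
- name: carer_distant
  mean: 56419.0
  low: 50777.0
  high: 62061.0
  family: gamma
  unit: AU$
  label: Carer costs, metastatic disease
- name: carer_local
  mean: 29295.0
  low: 26365.0
  high: 32224.0
  family: gamma
  unit: AU$
  label: Carer costs, locoregional disease
- name: carer_early
  mean: 2170.0
  low: 1953.0
  high: 2387.0
  family: gamma
  unit: AU$
  label: Carer costs, early stage (annual)
- name: u_early
  mean: 0.818
  low: 0.718
  high: 0.918
  family: beta
  unit: utility
  label: Utility, early-stage breast cancer
- name: u_add_exercise
  mean: 0.07
  low: 0.04
  high: 0.1
  family: beta
  unit: utility
  label: Additional utility, exercise arm (first year)
- name: u_add_usual
  mean: 0.02
  low: 0.0
  high: 0.06
  family: beta
  unit: utility
  label: Additional utility, usual care (first year)
- name: u_local
  mean: 0.67
  low: 0.567
  high: 0.767
  family: beta
  unit: utility
  label: Utility, local recurrence
- name: u_distant
  mean: 0.64
  low: 0.54
  high: 0.74
  family: beta
  unit: utility
  label: Utility, distant recurrence
- name: u_terminal
  mean: 0.514
  low: 0.414
  high: 0.614
  family: beta
  unit: utility
  label: Utility, terminal breast cancer
- name: start_age
  mean: 52.0
  low: 44.0
  high: 60.0
  family: fixed
  unit: years
  label: Age entering the model
settings:
  start_age: 52.0
  discount_rate: 0.05
  cycle_length: 1.0
  horizon_age: 100.0
  min_alive: 0.001
  trial_window_years: 8.0
  psa_iterations: 5000.0
  wtp_threshold: 50000.0
  half_cycle: endpoints
  early_costs_annual: yes
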
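risks:
  rvte:
    p_first6: 0.018
    p_first6_low: 0.014
    p_first6_high: 0.022
    p_later: 0.002
    p_later_low: 0.0
    p_later_high: 0.004
    or_first6: 0.83
    or_first6_low: 0.59
    or_first6_high: 1.17
    or_later: 0.82
    or_later_low: 0.25
    or_later_high: 2.68
    sig_first6: no
    sig_later: no
  crnmb:
    p_first6: 0.017
    p_first6_low: 0.014
    p_first6_high: 0.02
    p_later: 0.004
    p_later_low: 0.002
    p_later_high: 0.006
    or_first6: 0.78
    or_first6_low: 0.66
    or_first6_high: 0.93
    or_later: 0.89
    or_later_low: 0.59
    or_later_high: 1.32
    sig_first6: yes
    sig_later: no
  mb:
    p_first6: 0.0016
    p_first6_low: 0.0007
    p_first6_high: 0.0026
    p_later: 0.0004
    p_later_low: 0.0
    p_later_high: 0.001
    or_first6: 1.15
    or_first6_low: 0.75
    or_first6_high: 1.75
    or_later: 0.44
    or_later_low: 0.13
    or_later_high: 1.42
    sig_first6: no
    sig_later: yes
  ich:
    p_first6: 0.0003
    p_first6_low: 0.0
    p_first6_high: 0.0008
    p_later: 0.0003
    p_later_low: 0.0
    p_later_high: 0.0008
    or_first6: 0.23
    or_first6_low: 0.07
    or_first6_high: 0.81
    or_later: 0.39
    or_later_low: 0.08
    or_later_high: 2.02
    sig_first6: yes
    sig_later: no
clinical:
  prop_index_pe: 0.401
  prop_index_pe_with_dvt: 0.441
  prop_recurrence_pe: 0.565
  p_recur_off_treatment: 0.0042
  p_cteph_after_pe: 0.048
  p_pts_after_dvt: 0.027
  p_disabled_after_ich: 0.65
  cfr_pe_recurrence: 0.061
  cfr_non_ich_mb: 0.061
  cfr_ich: 0.261
  cfr_endarterectomy: 0.044
  p_monthly_death_post_ich_disability: 0.033
  p_monthly_death_cteph: 0.007
  prop_cteph_endarterectomy: 0.503
utilities:
  u_pe: 0.67
  u_dvt: 0.71
  du_warfarin: 0.0137
  du_crnmb: 0.05
  du_non_ich_mb: 0.3158
  du_ich: 0.6526
  du_ich_disability: 0.6526
  du_cteph: 0.3
  du_pts: 0.1368
  du_rvte_first_month: 0.14
costs:
  c_warfarin_cycle_first: 273.81
  c_warfarin_cycle_later: 26.73
  c_edoxaban_cycle_first: 108.62
  c_edoxaban_cycle_later: 53.27
  c_warfarin_monthly_drug: 1.22
  c_edoxaban_monthly_first: 44.5
  c_edoxaban_monthly_later: 53.3
  c_heparin_daily: 12.82
  heparin_days_warfarin: 6.5
  heparin_days_edoxaban: 5.0
  c_inr_first: 87.0
  c_inr_subsequent: 26.0
  n_inr_titration: 4.0
  n_inr_monthly: 1.0
  c_pe_event: 1647.0
  c_dvt_event: 551.0
  c_ich_acute: 3012.0
  c_non_ich_mb: 2940.0
  c_crnmb: 384.0
  c_ich_disability_monthly: 524.0
  c_pts_first_month: 168.0
  c_pts_monthly: 23.0
  c_endarterectomy: 7824.0
  c_cteph_drugs_monthly: 1348.0
settings:
  horizon_months: 600.0
  discount_rate_annual: 0.035
  wtp: 20000.0
  start_age: 56.0
  prop_male: 0.57
  initial_treatment_months: 6.0
  recurrence_treatment_months: 6.0
  subgroup: all
  or_nonsig_to_one: no
  half_cycle_correction: no
  use_age_utility: yes
  du_warfarin_scope: all
  rvte_or_in_base: no
  lifelong_common: yes
  rng_seed: 20180717.0
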
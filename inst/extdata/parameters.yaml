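# Default model inputs for the social anxiety disorder cost-utility model.
# Every field can be overridden through sad_parameters(...).
treatment_weeks: 12
post_treatment_weeks_y1: 52        # the decision tree covers treatment plus one full post-treatment year
horizon_years_post_treatment: 5    # 1 year decision tree + (horizon - 1) yearly Markov cycles
discount_rate: 0.035
wtp_threshold: 20000
n_iterations: 10000

utility_recovered:
  mean: 0.866                      # point estimate used at means
  beta: {alpha: 4572, beta: 707}   # probabilistic distribution
utility_sad:
  mean: 0.659
  beta: {alpha: 40, beta: 20}

annual_cost_recovered: {mean: 645, se: 93}     # gamma, GBP/year
annual_cost_sad: {mean: 1037, se: 209}

relapse_drug_y1:                   # midpoint of two pooled relapse risks (beta counts)
  first: {alpha: 107, beta: 293}
  second: {alpha: 222, beta: 170}
relapse_rr_drug_vs_psych: {mean: 3.00, ci_low: 0.73, ci_high: 12.39}   # log-normal
relapse_waitlist_y1: 0.0409        # unreported by the source; defaults to the annualised years-2-5 relapse
recovery_y2_5_12yr: {alpha: 65, beta: 111}     # 12-year beta, annualised by constant hazard
relapse_y2_5_12yr: {alpha: 26, beta: 40}

gp_visit_unit_cost: 46.75
therapist_unit_cost_band7: 110
therapist_unit_cost_band6: 93
therapist_unit_cost_band5: 87

gp_visits_initial:                 # categorical; 65%: 4; 10%: 3, 5 or 6; 25%: 1 or 2
  point: 4
  values: [4, 3, 5, 6, 1, 2]
  probs: [0.65, 0.0333333333333333, 0.0333333333333333, 0.0333333333333333, 0.125, 0.125]
gp_visits_maintenance:             # categorical; 55%: 3; 45%: 0, 1, 2 or 4
  point: 3
  values: [3, 0, 1, 2, 4]
  probs: [0.55, 0.1125, 0.1125, 0.1125, 0.1125]

selfhelp_minutes_sd_factor: 0.3    # SD of therapist contact time = 0.3 x mean

baseline_log_odds: {mean: -2.629, variance: 1.235}   # wait-list log-odds of recovery
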
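# Full default configuration of the troponinCEA model (2020 EUR).
# Every field may be overridden; unknown keys are rejected.
cost:
  ems_cost_per_transport: 559        # EUR per ambulance transport
  p_ambulance_to_primary: 0.29       # P(ambulance to primary care clinic)
  p_ambulance_to_hospital_base: 0.90
  p_ambulance_to_hospital_conservative: 0.75
  consultation_cost: 166             # shared consultation / general costs
  algorithm_lab_cost: 41             # lab + additional diagnostics
  personnel_cost_wage: 99            # personnel time, costed by wages
  personnel_cost_tariff: 137         # personnel time, costed by tariffs
  outpatient_referral_cost: 52       # outpatient cardiac testing referrals
  drg_total: 840664                  # total DRG, low-risk hospital cohort
  n_hospital_cohort: 567
  nok_per_eur: 10.73                 # 2020 exchange rate
  payroll_multiplier: 1.3            # payroll taxes and social charges
  helfo_multiplier: 2.0              # HELFO reimbursement gross-up
time:
  los_primary_base_mean_h: 3.4
  los_primary_base_sd_h: 0.740
  los_primary_conservative_mean_h: 4.0
  los_primary_conservative_sd_h: 0.870
  los_hospital_mean_h: 22.3
  los_hospital_sd_h: 22.010
  hours_per_year: 8766               # 365.25 * 24
utility:
  waiting_utility_decrement: 0.232   # utility lost per year of waiting
  qaly_loss_per_event: 2.222         # discounted lifetime QALYs per event
  remaining_qalys_no_event: 13.3
  remaining_qalys_post_ami: 11.1
  state_utilities:
    non_cvd: 0.87
    cvd: 0.80
events:
  rate_primary_30d: 0.003367003      # 5 / 1485
  rate_hospital_30d: 0.002320186     # 2 / 862
  excess_rate_conservative: 0.001
  base_case_event_loss_zero: true
economics:
  discount_rate: 0.04
  threshold_low: 25600               # EUR per QALY
  threshold_high: 76900
  reference_year: 2020
markov:
  start_age: 56
  gompertz_b: 2.0e-05
  gompertz_theta: 0.095
  hazard_ratio: 1.6                  # CVD vs non-CVD mortality
  cvd_incidence: 0.01                # annual, from non-CVD
  max_age: 110
  mortality_scale: 1
  utility_scale: 1
  discount_from_cycle: 1
induced_testing_fraction: 0.15       # sensitivity use only (range 0.10-0.15)
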
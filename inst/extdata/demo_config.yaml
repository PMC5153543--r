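# Demonstration two-arm pipeline configuration.
# Relative paths are resolved against the directory holding this file.
seed: 42
arms:
  - arm_label: cotrimoxazole
    n_patients: 60
    followup_days: 672
    mortality_prob: 0.3483
    physician_visit_rate: 11.0
    nursing_visit_rate: 0.65
    hosp_episode_rate: 1.2
    los_distribution: {meanlog: 1.6, sdlog: 0.9, cap: 77}
  - arm_label: arv
    n_patients: 60
    followup_days: 336
    mortality_prob: 0.1043
    physician_visit_rate: 14.2
    nursing_visit_rate: 8.0
    hosp_episode_rate: 0.15
    los_distribution: {meanlog: 1.2, sdlog: 0.8, cap: 37}
prices:
  drug_tables:
    - arv_unit_prices.csv
    - oi_drug_unit_prices.csv
oi_table: oi_staging_conditions.csv
overhead:
  ledger: demo_overhead_ledger.csv
  assets: demo_capital_assets.csv
  annuity_rate: 0.03
  space_share: 0.25
  patient_load_share: 0.2
  capital_weight: 0.01
  basis_by_line:
    administration: space_share
    security: space_share
    utilities: space_share
    catering: patient_load_share
    laundry: patient_load_share
  bed_days_per_year: 3650
  horizon_weeks: 96
wages:
  physician: {monthly_wage: 1600, monthly_hours: 160, visit_duration: 0.5}
  nurse: {monthly_wage: 640, monthly_hours: 160, visit_duration: 0.5}
lab:
  mode: flat
  flat_rate: 15
outpatient_fixed_share: 0
bootstrap:
  n_resamples: 2000
  level: 0.95
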
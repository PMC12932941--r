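n_patients: 50
seed: 4217
first_day: '2022-02-01'
last_day: '2024-05-31'
criterion_prevalences:
  lung_disease: 0.12
  acute_respiratory_infection: 0.03
  obstructive_sleep_apnea: 0.12
  low_preop_spo2: 0.05
  airway_pathology: 0.03
  bmi_gt_40: 0.08
  multiple_intubation_attempts: 0.04
  long_surgery: 0.45
  surgical_site: 0.25
  bmi_gt_35: 0.1
  low_hemoglobin: 0.08
exclusion_prevalences:
  age_lt_18: 0.02
  pregnant_lactating: 0.015
  neuromuscular_disease: 0.015
  gfr_lt_30: 0.03
  sugammadex_allergy: 0.01
  planned_postop_intubation: 0.02
  non_intubated: 0.05
  emergency: 0.04
late_documentation_prob: 0.5
boundary_negative_rate: 0.15
site_mix:
  main_campus: 0.55
  west_campus: 0.35
  ambulatory_center: 0.1
team_mix:
  full_team: 0.15
  attending_crna: 0.25
  attending_resident: 0.4
  solo_attending: 0.2
start_hour_weights:
  '6': 2.0
  '7': 10.0
  '8': 14.0
  '9': 12.0
  '10': 10.0
  '11': 10.0
  '12': 9.0
  '13': 9.0
  '14': 8.0
  '15': 6.0
  '16': 4.0
  '17': 3.0
  '18': 2.0
  '19': 1.0
n_providers: 120
provider_team_consistency: 0.8
delay_probabilities:
  patient: 0.1
  scheduling: 0.12
  staff: 0.06
disposition_model:
  icu_direct: 0.03
  icu_unplanned: 0.08
  floor: 0.0
rocuronium_probability: 0.686
adherence_model:
  team_propensity:
    full_team: 0.574
    attending_crna: 0.569
    attending_resident: 0.526
    solo_attending: 0.422
  provider_concentration: 10.0
  solo_bimodal: yes
  solo_component_means:
  - 0.15
  - 0.75
  covariate_log_odds:
    long_surgery: 0.3
    delay_patient: 0.31
    delay_scheduling: 0.25
    delay_staff: -0.54
    low_hemoglobin: 0.85
    low_preop_spo2: -0.73
    bmi_gt_40: 0.37
    age_per_decade: -0.05
  stock_bypass_share: 0.9
noise_rate: 0.5
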
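# Criterion definitions for the respiratory-risk inclusion phenotype and the
# exclusion screen. Thresholds are strict inequalities as printed; windows are
# fixed day/hour counts measured backward from the scheduled case start so that
# evaluation is deterministic. Audits can diff this file against the source
# criterion table.
version: 1
inclusion_rule:
  majors_required: 1
  minors_required: 2
windows:
  acute_infection_days: 30      # "within 1 month of surgery"
  hemoglobin_days: 183          # "in the past 6 months"
  spo2_hours: 12                # "in the 12 hours prior to surgery"
thresholds:
  spo2_mean_lt: 95              # percent, strict <
  bmi_major_gt: 40              # kg/m^2, strict >
  bmi_minor_gt: 35              # kg/m^2, strict >
  hemoglobin_lt: 10             # g/dL, strict <
  duration_gt_min: 120          # minutes, strict > ("more than 2 hours")
  ventilator_gt_hours: 24       # strict > ("more than 24 hours")
  intubation_attempts_gt: 1     # strict > ("more than 1 attempt")
exclusion_thresholds:
  age_lt_years: 18
  gfr_lt: 30
surgical_site:
  excluded_service: Neurosurgery
  excluded_name_token: transplant          # case-insensitive substring
  head_neck_rule: both                     # both | either: tokens that disqualify
  head_neck_tokens: [Mastoid, Tympano]
  service_tokens:
    General Surgery: [Gastric, Liver, Pancreas, Hepat, Chole]
    Thoracic Surgery: [Pulm, Resection, Esoph, VATS, Lobe, Thoracotomy]
  head_neck_service: Head and Neck
  cpt_set: upper_abdominal_laparoscopic
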
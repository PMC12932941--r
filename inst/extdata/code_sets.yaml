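# ICD-10 / CPT code sets used by the respiratory-risk eligibility phenotype.
# Token grammar:
#   bare root   "J40"       the code itself and all descendants
#   range       "J41-J41.8" per-category inclusive range (J41, J41.0..J41.8,
#                           and descendants of J41.8; J41.9 excluded)
#   wildcard    "J09.x"     explicit all-descendants form of the root
version: 1
code_sets:
  obstructive_restrictive_lung_disease:
    description: >
      Current or historical obstructive or restrictive lung disease:
      bronchitis, emphysema, COPD, bronchiectasis, pulmonary fibrosis,
      sarcoidosis of lung.
    tokens:
      - J40
      - J41-J41.8
      - J42
      - J43-J43.9
      - J44-J44.9
      - J45
      - J47-J47.9
      - J84.1
      - J84.9
      - D86
  acute_respiratory_infection:
    description: >
      Acute nasopharyngitis, acute upper respiratory infections, pneumonia,
      bronchitis.
    tokens:
      - J00
      - J06-J06.9
      - J09
      - J09.x
      - J10-J10.89
      - J12-J12.9
      - J15-J15.9
      - J16-J16.8
      - J17
      - J18-J18.9
      - J20-J20.9
  obstructive_sleep_apnea:
    description: Obstructive sleep apnea (adult/pediatric).
    tokens:
      - G47.33
cpt_sets:
  upper_abdominal_laparoscopic:
    description: >
      Laparoscopic sleeve gastrectomy, laparoscopic cholecystectomy,
      laparoscopic Roux-en-Y, removal of lap band.
    tokens:
      - "43775"
      - "47562"
      - "43644"
      - "43774"
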
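# One fact at a time: a default patient/case meets nothing; each block
# perturbs a single fact and checks the verdict and its boundary.

test_that("diagnosis-driven major criteria fire on set membership", {
  d <- toy_dataset(diagnoses = dx_row("P1", "J44.9", "2020-01-01"))
  r <- screen1(d)
  expect_true(r$lung_disease)
  expect_equal(r$majors_met, 1L)
  expect_true(r$included) # one major suffices

  # preop-evaluation flag alone suffices too
  r <- screen1(toy_dataset(patients = base_patient(preop_copd = TRUE)))
  expect_true(r$lung_disease && r$included)

  # OSA: exactly G47.33 (or the flag); sibling codes do not count
  expect_true(screen1(toy_dataset(
    diagnoses = dx_row("P1", "g47.33", "2018-03-01")
  ))$obstructive_sleep_apnea)
  expect_false(screen1(toy_dataset(
    diagnoses = dx_row("P1", "G47.30", "2018-03-01")
  ))$obstructive_sleep_apnea)

  # future-dated diagnoses are invisible at evaluation time
  expect_false(screen1(toy_dataset(
    diagnoses = dx_row("P1", "J44.9", "2023-06-01")
  ))$lung_disease)
})

test_that("acute respiratory infection honors the 30-day window", {
  met <- function(onset) {
    screen1(toy_dataset(
      diagnoses = dx_row("P1", "J18.9", onset)
    ))$acute_respiratory_infection
  }
  expect_true(met("2023-05-01")) # 9 days before
  expect_true(met("2023-04-10")) # exactly 30 days before
  expect_false(met("2023-04-09")) # 31 days: outside
  expect_true(screen1(toy_dataset(
    patients = base_patient(preop_recent_uri = TRUE)
  ))$acute_respiratory_infection)
})

test_that("SpO2 criterion takes the 12-hour window mean, strictly < 95", {
  vit <- function(vals, hours_before) {
    tibble::tibble(
      patient_id = "P1", kind = "spo2", value = vals,
      observed_at = ts("2023-05-10 09:00:00") - hours_before * 3600
    )
  }
  expect_false(screen1(toy_dataset(vitals = vit(c(94, 96), c(2, 4))))$low_preop_spo2)
  expect_true(screen1(toy_dataset(vitals = vit(c(94, 95.8), c(2, 4))))$low_preop_spo2)
  # no samples in the window: criterion is false, not an error
  expect_false(screen1(toy_dataset(vitals = vit(90, 13)))$low_preop_spo2)
  expect_false(screen1(toy_dataset())$low_preop_spo2)
  # samples outside the window never contaminate the mean
  both <- dplyr::bind_rows(vit(96, 2), vit(80, 20))
  expect_false(screen1(toy_dataset(vitals = both))$low_preop_spo2)
})

test_that("airway history and intubation attempts use strict thresholds", {
  vent <- function(h) {
    screen1(toy_dataset(
      patients = base_patient(vent_hours_pre_admission = h)
    ))$airway_pathology
  }
  expect_false(vent(24))
  expect_true(vent(24.5))
  expect_true(screen1(toy_dataset(
    patients = base_patient(tracheostomy_pre_admission = TRUE)
  ))$airway_pathology)
  att <- function(k) {
    screen1(toy_dataset(
      patients = base_patient(prior_max_intubation_attempts = k)
    ))$multiple_intubation_attempts
  }
  expect_false(att(1L))
  expect_true(att(2L))
})

test_that("admission BMI uses the latest observation and strict cutoffs", {
  bmi_at <- function(values, hours_before) {
    toy_dataset(bmi_observations = tibble::tibble(
      patient_id = "P1",
      observed_at = ts("2023-05-10 09:00:00") - hours_before * 3600,
      bmi = values
    ))
  }
  r <- screen1(bmi_at(40, 5))
  expect_false(r$bmi_gt_40)
  expect_true(r$bmi_gt_35) # exactly 40: only the >35 tier
  r <- screen1(bmi_at(40.1, 5))
  expect_true(r$bmi_gt_40 && r$bmi_gt_35)
  expect_false(any(screen1(bmi_at(35, 5))[c("bmi_gt_35", "bmi_gt_40")] == TRUE))
  # latest-before-start wins over older observations
  r <- screen1(bmi_at(c(45, 32), c(24 * 30, 5)))
  expect_false(r$bmi_gt_35)
  # observations after the scheduled start are ignored
  r <- screen1(bmi_at(c(45), c(-5)))
  expect_false(r$bmi_gt_40)
})

test_that("hemoglobin criterion is < 10 g/dL within 183 days", {
  lab <- function(value, days_before) {
    toy_dataset(labs = tibble::tibble(
      patient_id = "P1", analyte = "hemoglobin_serum", value = value,
      collected_at = ts("2023-05-10 09:00:00") - days_before * 86400
    ))
  }
  expect_true(screen1(lab(9.9, 30))$low_hemoglobin)
  expect_false(screen1(lab(10, 30))$low_hemoglobin) # strict <
  expect_false(screen1(lab(8, 200))$low_hemoglobin) # stale
  expect_true(screen1(lab(8, 183))$low_hemoglobin) # window edge
})

test_that("scheduled duration > 2 hours is strict", {
  dur <- function(m) {
    screen1(toy_dataset(cases = base_case(scheduled_duration_min = m)))
  }
  expect_false(dur(120)$long_surgery)
  expect_true(dur(121)$long_surgery)
})

test_that("surgical-site rule follows the service/name/CPT table", {
  site <- function(service, name, cpt = "") {
    screen1(toy_dataset(cases = base_case(
      service = service, procedure_name = name, cpt_codes = cpt
    )))$surgical_site
  }
  expect_true(site("Thoracic Surgery", "VATS right upper lobe"))
  expect_true(site("General Surgery", "Laparoscopic Cholecystectomy"))
  expect_true(site("General Surgery", "open hepatectomy")) # case-insensitive
  expect_false(site("General Surgery", "Inguinal hernia repair"))
  expect_true(site("Head and Neck", "Neck dissection"))
  expect_false(site("Head and Neck", "Tympanomastoidectomy")) # both tokens
  expect_true(site("Head and Neck", "Mastoidectomy")) # only one token
  expect_false(site("Neurosurgery", "Craniotomy")) # excluded service
  expect_false(site("General Surgery", "Liver transplant")) # transplant bar
  expect_true(site("General Surgery", "Bariatric procedure", cpt = "43775"))
  expect_false(site("General Surgery", "Bariatric procedure", cpt = "99999"))
})

test_that("the head-and-neck disqualifier is configurable to either-token", {
  d <- withr::local_tempdir()
  src <- system.file("extdata", "criteria.yaml", package = "periscreen")
  cfg_txt <- sub("head_neck_rule: both", "head_neck_rule: either", readLines(src))
  writeLines(cfg_txt, file.path(d, "criteria.yaml"))
  cfg <- screening_config(criteria_path = file.path(d, "criteria.yaml"))
  r <- screen1(toy_dataset(cases = base_case(
    service = "Head and Neck", procedure_name = "Mastoidectomy"
  )), config = cfg)
  expect_false(r$surgical_site)
})

test_that("inclusion needs one major or two minors", {
  # 0 major, 1 minor
  r <- screen1(toy_dataset(cases = base_case(scheduled_duration_min = 200)))
  expect_equal(r$minors_met, 1L)
  expect_false(r$included)
  # 0 major, 2 minor
  r <- screen1(toy_dataset(cases = base_case(
    scheduled_duration_min = 200,
    service = "Thoracic Surgery", procedure_name = "Esophagectomy"
  )))
  expect_equal(r$minors_met, 2L)
  expect_true(r$included)
  # 1 major, 0 minor
  r <- screen1(toy_dataset(patients = base_patient(preop_sleep_apnea = TRUE)))
  expect_equal(c(r$majors_met, r$minors_met), c(1L, 0L))
  expect_true(r$included)
})

test_that("exclusions: age, GFR, allergy, plans, ICU and emergency", {
  excl <- function(data) screen1(data)
  # 18th birthday is the boundary: the day before still excludes
  p <- base_patient(birth_date = as.Date("2005-05-11")) # 17 y 364 d at start
  expect_true(excl(toy_dataset(patients = p))$excl_age_lt_18)
  p <- base_patient(birth_date = as.Date("2005-05-10")) # exactly 18
  expect_false(excl(toy_dataset(patients = p))$excl_age_lt_18)

  expect_false(excl(toy_dataset(
    patients = base_patient(gfr_latest = 30)
  ))$excl_gfr_lt_30)
  expect_true(excl(toy_dataset(
    patients = base_patient(gfr_latest = 29.9)
  ))$excl_gfr_lt_30)
  expect_false(excl(toy_dataset(
    patients = base_patient(gfr_latest = NA_real_)
  ))$excl_gfr_lt_30)

  expect_true(excl(toy_dataset(
    patients = base_patient(allergies = "penicillin;Sugammadex")
  ))$excl_sugammadex_allergy)
  expect_false(excl(toy_dataset(
    patients = base_patient(allergies = "penicillin")
  ))$excl_sugammadex_allergy)

  expect_true(excl(toy_dataset(
    cases = base_case(airway_plan = "non_intubated")
  ))$excl_non_intubated)
  expect_true(excl(toy_dataset(
    cases = base_case(emergency = TRUE)
  ))$excl_emergency)
  expect_true(excl(toy_dataset(
    cases = base_case(planned_postop_intubation = TRUE)
  ))$excl_planned_postop_intubation)

  # planned ICU admission excludes; an unplanned transfer does not
  expect_true(excl(toy_dataset(
    cases = base_case(disposition = "icu_direct", pacu_los_min = NA_real_)
  ))$excl_direct_icu_admission)
  r <- excl(toy_dataset(
    cases = base_case(disposition = "icu_unplanned_transfer")
  ))
  expect_false(r$excluded_any)
})

test_that("late-documented patient exclusions are invisible until documented", {
  p <- base_patient(
    pregnant_or_lactating = TRUE, sex = "female",
    exclusion_documented_at = ts("2023-05-11 12:00:00") # day after surgery
  )
  d <- toy_dataset(patients = p)
  expect_false(screen1(d)$excl_pregnant_lactating)
  post <- screen_exclusions(d, as_of = "post_hoc")
  expect_true(post$pregnant_lactating[1])
})

test_that("verdicts are invariant to fact storage order", {
  co <- generate_cohort(sim_config(n_patients = 120, seed = 31))
  data <- co$data
  set.seed(99)
  shuffled <- ehr_dataset(
    patients = data$patients[sample(nrow(data$patients)), ],
    diagnoses = data$diagnoses[sample(nrow(data$diagnoses)), ],
    labs = data$labs[sample(nrow(data$labs)), ],
    vitals = data$vitals[sample(nrow(data$vitals)), ],
    bmi_observations = data$bmi_observations[sample(nrow(data$bmi_observations)), ],
    cases = data$cases, meds = data$meds
  )
  a <- screen_cases(data)
  b <- screen_cases(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b[match(a$case_id, b$case_id), ]),
    ignore_attr = TRUE
  )
})

test_that("adding a major fact never un-includes; no facts means not included", {
  base <- toy_dataset()
  expect_false(screen1(base)$included)
  expect_equal(screen1(base)$majors_met + screen1(base)$minors_met, 0L)
  co <- generate_cohort(sim_config(n_patients = 60, seed = 17))
  dec0 <- screen_cases(co$data)
  with_osa <- co$data
  with_osa$diagnoses <- dplyr::bind_rows(
    with_osa$diagnoses,
    dx_row(co$data$patients$patient_id, "G47.33", "2015-01-01")
  )
  dec1 <- screen_cases(ehr_dataset(
    patients = with_osa$patients, diagnoses = with_osa$diagnoses,
    labs = with_osa$labs, vitals = with_osa$vitals,
    bmi_observations = with_osa$bmi_observations, cases = with_osa$cases,
    meds = with_osa$meds
  ))
  expect_true(all(dec1$included))
  expect_true(all(dec1$included >= dec0$included))
})

test_that("counting identity holds on every screened case", {
  co <- generate_cohort(sim_config(n_patients = 400, seed = 23))
  dec <- screen_cases(co$data)
  crit <- criterion_definitions()
  majors <- rowSums(as.matrix(dec[crit$criterion_id[crit$tier == "major"]]))
  minors <- rowSums(as.matrix(dec[crit$criterion_id[crit$tier == "minor"]]))
  expect_equal(dec$majors_met, as.integer(majors))
  expect_equal(dec$minors_met, as.integer(minors))
  expect_equal(dec$included, majors >= 1 | minors >= 2)
})

test_that("engine agrees with the naive oracle on a randomized cohort", {
  co <- generate_cohort(sim_config(n_patients = 800, seed = 12))
  dec <- screen_cases(co$data)
  ref <- naive_screen(co$data)
  i <- match(dec$case_id, ref$case_id)
  expect_equal(dec$majors_met, ref$majors[i])
  expect_equal(dec$minors_met, ref$minors[i])
  expect_equal(dec$included, ref$included[i])
  expect_equal(dec$excluded_any, ref$excluded[i])
})

test_that("evaluate_case reports evidence for every met criterion", {
  d <- toy_dataset(
    patients = base_patient(preop_sleep_apnea = TRUE),
    diagnoses = dx_row("P1", "J44.9", "2020-01-01"),
    cases = base_case(scheduled_duration_min = 180)
  )
  dec <- evaluate_case(d, "C1")
  expect_s3_class(dec, "eligibility_decision")
  expect_true(dec$included)
  met <- dec$criterion_results[dec$criterion_results$met, ]
  expect_gte(nrow(met), 3)
  expect_true(all(lengths(met$evidence) > 0))
  expect_output(print(dec), "INCLUDED")
  expect_error(evaluate_case(d, "NOPE"), "unknown case_id")
})
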
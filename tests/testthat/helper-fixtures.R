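# Hand-built dataset fixtures: a default adult patient / routine case with
# no criteria met, which individual tests perturb.

ts <- function(x) as.POSIXct(x, tz = "UTC")

base_patient <- function(patient_id = "P1", ...) {
  defaults <- list(
    patient_id = patient_id,
    birth_date = as.Date("1970-06-15"),
    sex = "male",
    pregnant_or_lactating = FALSE,
    allergies = "",
    preop_copd = FALSE, preop_supplemental_o2 = FALSE,
    preop_lung_transplant = FALSE, preop_recent_uri = FALSE,
    preop_sleep_apnea = FALSE,
    neuromuscular_disease = FALSE,
    gfr_latest = 90,
    vent_hours_pre_admission = 0,
    tracheostomy_pre_admission = FALSE,
    prior_max_intubation_attempts = 0L,
    exclusion_documented_at = ts(NA)
  )
  mods <- list(...)
  defaults[names(mods)] <- mods
  tibble::as_tibble(defaults)
}

base_case <- function(case_id = "C1", patient_id = "P1", ...) {
  defaults <- list(
    case_id = case_id,
    patient_id = patient_id,
    site = "main_campus",
    scheduled_start = ts("2023-05-10 09:00:00"),
    scheduled_duration_min = 90,
    service = "Orthopedics",
    procedure_name = "Total knee arthroplasty",
    cpt_codes = "",
    emergency = FALSE,
    airway_plan = "intubated_general",
    planned_postop_intubation = FALSE,
    attending_id = "A1",
    crna_present = TRUE,
    resident_present = TRUE,
    delay_patient = FALSE, delay_scheduling = FALSE, delay_staff = FALSE,
    disposition = "pacu",
    unexpected_icu_transfer = FALSE,
    reintubation = FALSE,
    pacu_los_min = 60,
    min_spo2 = 97,
    death = FALSE
  )
  mods <- list(...)
  defaults[names(mods)] <- mods
  tibble::as_tibble(defaults)
}

toy_dataset <- function(patients = base_patient(), cases = base_case(),
                        diagnoses = NULL, labs = NULL, vitals = NULL,
                        bmi_observations = NULL, meds = NULL) {
  ehr_dataset(
    patients = patients, cases = cases, diagnoses = diagnoses, labs = labs,
    vitals = vitals, bmi_observations = bmi_observations, meds = meds
  )
}

dx_row <- function(patient_id, icd10, onset_date) {
  tibble::tibble(
    patient_id = patient_id, icd10 = icd10,
    onset_date = as.Date(onset_date)
  )
}

med_row <- function(case_id, drug, source = "na", at = "2023-05-10 10:30:00",
                    via_bpa = FALSE) {
  tibble::tibble(
    case_id = case_id, drug = drug, source = source,
    administered_at = ts(at), ordered_via_bpa = via_bpa
  )
}

# screen a one-perturbation dataset and return the single decision row
screen1 <- function(data, ...) screen_cases(data, ...)[1, ]
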
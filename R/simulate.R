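# Constructive synthetic EHR generator. The latent truth (which criteria and
# exclusions each case satisfies, what each provider intends to do) is
# sampled first and then realized as concrete facts that the rule engine
# will detect, so the ground-truth ledger is consistent with the emitted
# tables by construction. Negatives are realized so they do NOT trigger,
# with boundary-adjacent negatives (values exactly at a strict threshold,
# facts just outside a lookback window) generated at a configurable rate.

# dotted/cased variants exercise code normalization downstream
.lung_codes_pos <- c(
  "J40", "J41.0", "J41.8", "J42", "J43.2", "j44.9", "J44.1", "J45.909",
  "J45", "J47.9", "J84.1", "J84.9", "D86.0"
)
.lung_codes_near <- c("J41.9", "J46", "J84.8", "J85.0")
.ari_codes_pos <- c(
  "J00", "J06.9", "J09.X2", "J10.1", "J12.9", "J15.9", "J16.8", "J17",
  "J18.9", "j20.9"
)
.osa_codes_near <- c("G47.30", "G47.39", "G47.9")
.noise_codes <- c("I10", "E11.9", "K21.9", "M54.5", "F41.1")

.site_cases <- list(
  positive = list(
    list(service = "General Surgery", name = "Gastric bypass", cpt = ""),
    list(service = "General Surgery", name = "Liver resection, open", cpt = ""),
    list(service = "General Surgery", name = "Distal Pancreas resection", cpt = ""),
    list(service = "General Surgery", name = "Hepatectomy, partial", cpt = ""),
    list(service = "General Surgery", name = "Laparoscopic Cholecystectomy", cpt = "47562"),
    list(service = "General Surgery", name = "Bariatric procedure", cpt = "43775"),
    list(service = "General Surgery", name = "Revision of band", cpt = "43774"),
    list(service = "Thoracic Surgery", name = "VATS right upper lobe", cpt = ""),
    list(service = "Thoracic Surgery", name = "Pulmonary Lobectomy", cpt = ""),
    list(service = "Thoracic Surgery", name = "Esophagectomy", cpt = ""),
    list(service = "Thoracic Surgery", name = "Thoracotomy and decortication", cpt = ""),
    list(service = "Head and Neck", name = "Neck dissection", cpt = ""),
    list(service = "Head and Neck", name = "Total Thyroidectomy", cpt = ""),
    list(service = "Head and Neck", name = "Parotidectomy", cpt = "")
  ),
  negative = list(
    list(service = "Orthopedics", name = "Total knee arthroplasty", cpt = ""),
    list(service = "General Surgery", name = "Inguinal hernia repair", cpt = ""),
    list(service = "Urology", name = "Robotic prostatectomy", cpt = ""),
    list(service = "Thoracic Surgery", name = "Mediastinoscopy", cpt = ""),
    list(service = "OB/GYN", name = "Hysterectomy, abdominal", cpt = "")
  ),
  boundary = list(
    list(service = "Neurosurgery", name = "Craniotomy for tumor", cpt = ""),
    list(service = "Head and Neck", name = "Tympanomastoidectomy", cpt = ""),
    list(service = "General Surgery", name = "Liver transplant", cpt = "")
  )
)

#' Simulation configuration
#'
#' All knobs of the synthetic cohort: size, criterion and exclusion
#' prevalences, site/team mixes, scheduling, disposition model, and the
#' provider-behavior (adherence) model. True prevalences in the source
#' cohort are unpublished, so the defaults are labelled placeholders chosen
#' to give every criterion non-trivial representation; the team-conditional
#' adherence propensities default to the reported team-stratified rates.
#' A fixed seed makes the generated cohort bitwise identical across runs.
#'
#' @param n_patients Number of patients (one surgical case each).
#' @param seed Master RNG seed; every record-type stream derives from it.
#' @param first_day,last_day Calendar range of scheduled starts.
#' @param criterion_prevalences Named probabilities for the 11 criteria
#'   (`bmi_gt_35` is the probability of the 35-40 band given not > 40).
#' @param exclusion_prevalences Named probabilities for the exclusion flags.
#' @param late_documentation_prob Probability that a patient-level exclusion
#'   (pregnancy, neuromuscular disease, allergy, GFR) is documented only
#'   after the case, so an alert-time screen cannot see it (the mechanism
#'   behind misallocated alerts).
#' @param boundary_negative_rate Probability that a negative is realized at
#'   the decision boundary (e.g. SpO2 mean exactly 95, duration exactly
#'   120 min, GFR exactly 30).
#' @param site_mix,team_mix Named categorical distributions (normalized).
#' @param start_hour_weights Weights over starting hours 6..19.
#' @param n_providers Size of the attending pool.
#' @param provider_team_consistency Probability a case keeps its attending's
#'   primary team composition.
#' @param delay_probabilities Named probabilities for the three delay flags.
#' @param disposition_model Named probabilities for `icu_direct`,
#'   `icu_unplanned`, `floor`; the remainder recover in the PACU.
#' @param rocuronium_probability Probability a case receives rocuronium.
#' @param adherence_model List: `team_propensity` (per-team mean adherence
#'   propensity), `provider_concentration` (beta concentration of the
#'   provider-level mixture; `Inf` = every provider exactly at the team
#'   mean), `solo_bimodal` + `solo_component_means` (two-component mixture
#'   for solo attendings), `covariate_log_odds` (named effects applied on
#'   the log-odds scale), `stock_bypass_share` (probability a non-adherent
#'   response uses standard-stock sugammadex rather than no drug).
#' @param noise_rate Rate of irrelevant background facts per patient.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1L,
                       first_day = "2022-02-01",
                       last_day = "2024-05-31",
                       criterion_prevalences = c(
                         lung_disease = 0.12,
                         acute_respiratory_infection = 0.03,
                         obstructive_sleep_apnea = 0.12,
                         low_preop_spo2 = 0.05,
                         airway_pathology = 0.03,
                         bmi_gt_40 = 0.08,
                         multiple_intubation_attempts = 0.04,
                         long_surgery = 0.45,
                         surgical_site = 0.25,
                         bmi_gt_35 = 0.10,
                         low_hemoglobin = 0.08
                       ),
                       exclusion_prevalences = c(
                         age_lt_18 = 0.02,
                         pregnant_lactating = 0.015,
                         neuromuscular_disease = 0.015,
                         gfr_lt_30 = 0.03,
                         sugammadex_allergy = 0.01,
                         planned_postop_intubation = 0.02,
                         non_intubated = 0.05,
                         emergency = 0.04
                       ),
                       late_documentation_prob = 0.5,
                       boundary_negative_rate = 0.15,
                       site_mix = c(
                         main_campus = 0.55, west_campus = 0.35,
                         ambulatory_center = 0.10
                       ),
                       team_mix = c(
                         full_team = 0.15, attending_crna = 0.25,
                         attending_resident = 0.40, solo_attending = 0.20
                       ),
                       start_hour_weights = c(
                         `6` = 2, `7` = 10, `8` = 14, `9` = 12, `10` = 10,
                         `11` = 10, `12` = 9, `13` = 9, `14` = 8, `15` = 6,
                         `16` = 4, `17` = 3, `18` = 2, `19` = 1
                       ),
                       n_providers = 120,
                       provider_team_consistency = 0.8,
                       delay_probabilities = c(
                         patient = 0.10, scheduling = 0.12, staff = 0.06
                       ),
                       disposition_model = c(
                         icu_direct = 0.03, icu_unplanned = 0.08, floor = 0
                       ),
                       rocuronium_probability = 0.686,
                       adherence_model = list(
                         team_propensity = c(
                           full_team = 0.574, attending_crna = 0.569,
                           attending_resident = 0.526, solo_attending = 0.422
                         ),
                         provider_concentration = 10,
                         solo_bimodal = TRUE,
                         solo_component_means = c(0.15, 0.75),
                         covariate_log_odds = c(
                           long_surgery = 0.30, delay_patient = 0.31,
                           delay_scheduling = 0.25, delay_staff = -0.54,
                           low_hemoglobin = 0.85, low_preop_spo2 = -0.73,
                           bmi_gt_40 = 0.37, age_per_decade = -0.05
                         ),
                         stock_bypass_share = 0.9
                       ),
                       noise_rate = 0.5) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      first_day = first_day, last_day = last_day,
      criterion_prevalences = criterion_prevalences,
      exclusion_prevalences = exclusion_prevalences,
      late_documentation_prob = late_documentation_prob,
      boundary_negative_rate = boundary_negative_rate,
      site_mix = site_mix, team_mix = team_mix,
      start_hour_weights = start_hour_weights,
      n_providers = as.integer(n_providers),
      provider_team_consistency = provider_team_consistency,
      delay_probabilities = delay_probabilities,
      disposition_model = disposition_model,
      rocuronium_probability = rocuronium_probability,
      adherence_model = adherence_model,
      noise_rate = noise_rate
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$criterion_prevalences, cfg$exclusion_prevalences,
    cfg$late_documentation_prob, cfg$boundary_negative_rate,
    cfg$provider_team_consistency, cfg$delay_probabilities,
    cfg$disposition_model, cfg$rocuronium_probability,
    cfg$adherence_model$team_propensity,
    cfg$adherence_model$stock_bypass_share, cfg$noise_rate
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("sim_config: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("sim_config: n_patients < 1", call. = FALSE)
  need <- criterion_definitions()$criterion_id
  if (!all(need %in% names(cfg$criterion_prevalences))) {
    stop("sim_config: criterion_prevalences must name all 11 criteria",
      call. = FALSE
    )
  }
  if (sum(cfg$disposition_model) > 1) {
    stop("sim_config: disposition probabilities exceed 1", call. = FALSE)
  }
  if (any(cfg$site_mix < 0) || sum(cfg$site_mix) <= 0 ||
    any(cfg$team_mix < 0) || sum(cfg$team_mix) <= 0) {
    stop("sim_config: invalid categorical mix", call. = FALSE)
  }
  if (cfg$exclusion_prevalences[["pregnant_lactating"]] > 0.5) {
    stop("sim_config: pregnant_lactating prevalence not satisfiable",
      call. = FALSE
    )
  }
  invisible(cfg)
}

# derived per-record-type RNG streams (adding a field to one block never
# perturbs draws in another)
stream_seeds <- function(seed, n = 10L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed)
  force(expr)
}

rbern <- function(n, p) stats::runif(n) < p

#' Generate a synthetic cohort with its ground-truth ledger
#'
#' Samples the latent truth for every (patient, case) pair — which criteria
#' and exclusions hold, the care team, the attending's latent adherence
#' propensity, the intended response to an alert — then emits EHR-style
#' facts realizing that truth, plus a ledger recording it. Generation is
#' deterministic per seed.
#'
#' @param config A [sim_config()].
#' @param availability An [availability_config()]; used to record in the
#'   ledger whether each case is expected to alert under the default polls.
#' @return List of class `sim_cohort`: `data` (an `ehr_dataset`), `ledger`
#'   (tibble), `providers` (tibble), `config`.
#' @export
generate_cohort <- function(config = sim_config(),
                            availability = availability_config()) {
  validate_sim_config(config)
  n <- config$n_patients
  seeds <- stream_seeds(config$seed, 13L)
  prev <- config$criterion_prevalences
  exprev <- config$exclusion_prevalences
  bnd <- config$boundary_negative_rate

  patient_id <- sprintf("P%06d", seq_len(n))
  case_id <- sprintf("C%06d", seq_len(n))

  # --- schedule stream -----------------------------------------------------
  sched <- with_stream(seeds[1], {
    days <- as.integer(as.Date(config$last_day) - as.Date(config$first_day))
    day <- as.Date(config$first_day) + sample.int(days + 1L, n, TRUE) - 1L
    hrs <- as.integer(names(config$start_hour_weights))
    hour <- sample(hrs, n, TRUE, prob = config$start_hour_weights)
    minute <- sample.int(60L, n, TRUE) - 1L
    start <- as.POSIXct(
      paste0(format(day), sprintf(" %02d:%02d:00", hour, minute)),
      tz = "UTC"
    )
    site <- sample(names(config$site_mix), n, TRUE, prob = config$site_mix)
    list(start = start, start_date = day, site = site)
  })
  start <- sched$start
  start_date <- sched$start_date

  # --- demographics stream -------------------------------------------------
  demo <- with_stream(seeds[2], {
    minor <- rbern(n, exprev[["age_lt_18"]])
    days_old <- ifelse(
      minor,
      sample(3653L:6550L, n, TRUE), # 10 to <18 years
      sample(7000L:32850L, n, TRUE) # 19 to 90 years
    )
    sex <- sample(c("female", "male"), n, TRUE, prob = c(0.52, 0.48))
    list(birth_date = start_date - days_old, sex = sex, minor = minor)
  })

  # --- criterion truths ----------------------------------------------------
  truth <- with_stream(seeds[3], {
    t <- list()
    for (id in c(
      "lung_disease", "acute_respiratory_infection", "obstructive_sleep_apnea",
      "low_preop_spo2", "airway_pathology", "multiple_intubation_attempts",
      "long_surgery", "surgical_site", "low_hemoglobin"
    )) {
      t[[id]] <- rbern(n, prev[[id]])
    }
    t$bmi_gt_40 <- rbern(n, prev[["bmi_gt_40"]])
    t$bmi_gt_35 <- t$bmi_gt_40 | (!t$bmi_gt_40 & rbern(n, prev[["bmi_gt_35"]]))
    t
  })

  # --- realization streams -------------------------------------------------
  diag_rows <- list()
  lab_rows <- list()
  vital_rows <- list()
  bmi_rows <- list()

  realz <- with_stream(seeds[4], {
    # lung disease: diagnosis and/or preop flag
    lung_mode <- sample(3L, n, TRUE, prob = c(0.6, 0.25, 0.15)) # dx/flag/both
    lung_dx <- truth$lung_disease & lung_mode != 2L
    lung_flag <- truth$lung_disease & lung_mode != 1L
    idx <- which(lung_dx)
    diag_rows$lung <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.lung_codes_pos, length(idx), TRUE),
      onset_date = start_date[idx] - sample(40L:2000L, length(idx), TRUE)
    )
    idx <- which(!truth$lung_disease & rbern(n, bnd))
    diag_rows$lung_near <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.lung_codes_near, length(idx), TRUE),
      onset_date = start_date[idx] - sample(40L:2000L, length(idx), TRUE)
    )
    which_flag <- sample(3L, n, TRUE)
    preop_copd <- lung_flag & which_flag == 1L
    preop_o2 <- lung_flag & which_flag == 2L
    preop_tx <- lung_flag & which_flag == 3L

    # acute respiratory infection: in-window diagnosis or recent-URI flag
    ari_mode <- rbern(n, 0.7) # TRUE: diagnosis, FALSE: flag
    idx <- which(truth$acute_respiratory_infection & ari_mode)
    diag_rows$ari <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.ari_codes_pos, length(idx), TRUE),
      onset_date = start_date[idx] - sample(0L:30L, length(idx), TRUE)
    )
    preop_uri <- truth$acute_respiratory_infection & !ari_mode
    # boundary negative: matching code just outside the 30-day window
    idx <- which(!truth$acute_respiratory_infection & rbern(n, bnd))
    diag_rows$ari_old <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.ari_codes_pos, length(idx), TRUE),
      onset_date = start_date[idx] - sample(31L:90L, length(idx), TRUE)
    )

    # OSA
    osa_mode <- rbern(n, 0.6)
    idx <- which(truth$obstructive_sleep_apnea & osa_mode)
    diag_rows$osa <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = rep("G47.33", length(idx)),
      onset_date = start_date[idx] - sample(40L:2000L, length(idx), TRUE)
    )
    preop_apnea <- truth$obstructive_sleep_apnea & !osa_mode
    idx <- which(!truth$obstructive_sleep_apnea & rbern(n, bnd))
    diag_rows$osa_near <- tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.osa_codes_near, length(idx), TRUE),
      onset_date = start_date[idx] - sample(40L:2000L, length(idx), TRUE)
    )

    list(
      preop_copd = preop_copd, preop_o2 = preop_o2, preop_tx = preop_tx,
      preop_uri = preop_uri, preop_apnea = preop_apnea
    )
  })

  spo2_real <- with_stream(seeds[5], {
    boundary <- !truth$low_preop_spo2 & rbern(n, bnd)
    emit <- (truth$low_preop_spo2 | rbern(n, 0.4)) & !boundary
    # boundary negatives: a {94, 96} pair whose mean is exactly 95
    bidx <- which(boundary)
    rows_bnd <- tibble::tibble(
      patient_id = rep(patient_id[bidx], each = 2L),
      kind = "spo2",
      value = rep(c(94, 96), length(bidx)),
      observed_at = rep(start[bidx], each = 2L) -
        stats::runif(2L * length(bidx), 60, 11.8 * 3600)
    )
    # in-window samples jittered around a per-case target mean, then shifted
    # so the window mean equals the target (the criterion reads the mean)
    eidx <- which(emit)
    k <- sample(1:4, length(eidx), TRUE)
    target <- ifelse(
      truth$low_preop_spo2[eidx],
      stats::runif(length(eidx), 88, 94.5),
      stats::runif(length(eidx), 95.5, 99)
    )
    grp <- rep(seq_along(eidx), k)
    vals <- rep(target, k) + stats::runif(length(grp), -1.5, 1.5)
    vals <- vals - stats::ave(vals, grp) + rep(target, k)
    rows_in <- tibble::tibble(
      patient_id = rep(patient_id[eidx], k),
      kind = "spo2",
      value = round(pmin(100, pmax(0, vals)), 1),
      observed_at = rep(start[eidx], k) -
        stats::runif(length(grp), 60, 11.8 * 3600)
    )
    # out-of-window low samples for some negatives (window logic must matter)
    old <- which(!truth$low_preop_spo2 & rbern(n, 0.2))
    rows_old <- tibble::tibble(
      patient_id = patient_id[old], kind = "spo2",
      value = round(stats::runif(length(old), 88, 93), 1),
      observed_at = start[old] - stats::runif(length(old), 13, 72) * 3600
    )
    dplyr::bind_rows(rows_bnd, rows_in, rows_old)
  })
  vital_rows$spo2 <- spo2_real

  airway_real <- with_stream(seeds[6], {
    mode <- rbern(n, 0.7) # TRUE: ventilator, FALSE: tracheostomy
    vent <- ifelse(
      truth$airway_pathology & mode, stats::runif(n, 25, 300),
      ifelse(rbern(n, bnd), 24, stats::runif(n, 0, 20))
    )
    trach <- truth$airway_pathology & !mode
    attempts <- ifelse(
      truth$multiple_intubation_attempts, sample(2:4, n, TRUE),
      ifelse(rbern(n, 0.5), 1L, 0L)
    )
    list(vent = round(vent, 1), trach = trach, attempts = as.integer(attempts))
  })

  bmi_real <- with_stream(seeds[7], {
    bmi <- ifelse(
      truth$bmi_gt_40, stats::runif(n, 40.5, 55),
      ifelse(
        truth$bmi_gt_35, stats::runif(n, 35.5, 40),
        ifelse(rbern(n, bnd), 35, stats::runif(n, 19, 34.5))
      )
    )
    # boundary for the >40 threshold: a 35-40 positive sitting exactly at 40
    at40 <- truth$bmi_gt_35 & !truth$bmi_gt_40 & rbern(n, bnd)
    bmi[at40] <- 40
    obs_at <- start - stats::runif(n, 0.5, 30 * 24) * 3600
    extra <- which(rbern(n, 0.3))
    bmi_rows$main <- tibble::tibble(
      patient_id = patient_id, observed_at = obs_at, bmi = round(bmi, 1)
    )
    bmi_rows$older <- tibble::tibble(
      patient_id = patient_id[extra],
      observed_at = start[extra] - stats::runif(length(extra), 60, 365) * 86400,
      bmi = round(stats::runif(length(extra), 19, 45), 1)
    )
    bmi
  })

  hgb_real <- with_stream(seeds[8], {
    pos <- which(truth$low_hemoglobin)
    lab_rows$hgb_pos <- tibble::tibble(
      patient_id = patient_id[pos], analyte = "hemoglobin_serum",
      value = round(stats::runif(length(pos), 6, 9.9), 1),
      collected_at = start[pos] - sample(1L:180L, length(pos), TRUE) * 86400
    )
    kindn <- sample(3L, n, TRUE, prob = c(0.4, 0.3, 0.3))
    at_bnd <- which(!truth$low_hemoglobin & rbern(n, bnd) & kindn == 1L)
    lab_rows$hgb_at10 <- tibble::tibble( # exactly 10: strict < fails
      patient_id = patient_id[at_bnd], analyte = "hemoglobin_serum",
      value = rep(10, length(at_bnd)),
      collected_at = start[at_bnd] - sample(1L:180L, length(at_bnd), TRUE) * 86400
    )
    old_low <- which(!truth$low_hemoglobin & rbern(n, bnd) & kindn == 2L)
    lab_rows$hgb_old <- tibble::tibble( # low but outside the 183-day window
      patient_id = patient_id[old_low], analyte = "hemoglobin_serum",
      value = round(stats::runif(length(old_low), 7, 9.5), 1),
      collected_at = start[old_low] - sample(190L:400L, length(old_low), TRUE) * 86400
    )
    normal <- which(!truth$low_hemoglobin & rbern(n, 0.5))
    lab_rows$hgb_norm <- tibble::tibble(
      patient_id = patient_id[normal], analyte = "hemoglobin_serum",
      value = round(stats::runif(length(normal), 10.5, 16), 1),
      collected_at = start[normal] - sample(1L:180L, length(normal), TRUE) * 86400
    )
    invisible(NULL)
  })

  case_real <- with_stream(seeds[9], {
    dur <- ifelse(
      truth$long_surgery,
      sample(121L:480L, n, TRUE),
      ifelse(rbern(n, bnd), 120L, sample(30L:120L, n, TRUE))
    )
    pick <- function(pool, k) pool[sample(length(pool), k, TRUE)]
    combo <- vector("list", n)
    npos <- sum(truth$surgical_site)
    combo[truth$surgical_site] <- pick(.site_cases$positive, npos)
    neg_bnd <- !truth$surgical_site & rbern(n, bnd)
    combo[neg_bnd] <- pick(.site_cases$boundary, sum(neg_bnd))
    rest <- !truth$surgical_site & !neg_bnd
    combo[rest] <- pick(.site_cases$negative, sum(rest))
    list(
      duration = as.numeric(dur),
      service = vapply(combo, `[[`, "", "service"),
      proc_name = vapply(combo, `[[`, "", "name"),
      cpt = vapply(combo, `[[`, "", "cpt")
    )
  })

  # --- exclusion truths and realization ------------------------------------
  excl <- with_stream(seeds[10], {
    pregnant <- rbern(n, exprev[["pregnant_lactating"]]) &
      demo$sex == "female" & !demo$minor
    neuro <- rbern(n, exprev[["neuromuscular_disease"]])
    gfr_low <- rbern(n, exprev[["gfr_lt_30"]])
    gfr <- ifelse(
      gfr_low, round(stats::runif(n, 5, 29.9), 1),
      ifelse(rbern(n, bnd), 30, round(stats::runif(n, 45, 120), 1))
    )
    gfr[!gfr_low & rbern(n, 0.2)] <- NA # absent GFR never excludes
    allergy_sug <- rbern(n, exprev[["sugammadex_allergy"]])
    other_all <- rbern(n, 0.15)
    allergies <- join_list_col(Map(
      function(s, o) c(if (o) "penicillin", if (s) "sugammadex"),
      allergy_sug, other_all
    ))
    planned_tube <- rbern(n, exprev[["planned_postop_intubation"]])
    non_intub <- rbern(n, exprev[["non_intubated"]])
    emergency <- rbern(n, exprev[["emergency"]])
    u <- stats::runif(n)
    dm <- config$disposition_model
    disposition <- dplyr::case_when(
      u < dm[["icu_direct"]] ~ "icu_direct",
      u < dm[["icu_direct"]] + dm[["icu_unplanned"]] ~ "icu_unplanned_transfer",
      u < sum(dm) ~ "floor",
      .default = "pacu"
    )
    patient_excl <- pregnant | neuro | gfr_low | allergy_sug
    late <- patient_excl & rbern(n, config$late_documentation_prob)
    doc_at <- rep(as.POSIXct(NA, tz = "UTC"), n)
    doc_at[patient_excl & !late] <- start[patient_excl & !late] - 30 * 86400
    doc_at[late] <- start[late] + case_real$duration[late] * 60 + 86400
    list(
      pregnant = pregnant, neuro = neuro, gfr = gfr, gfr_low = gfr_low,
      allergies = allergies, allergy_sug = allergy_sug,
      planned_tube = planned_tube, non_intub = non_intub,
      emergency = emergency, disposition = disposition,
      late = late, doc_at = doc_at
    )
  })

  # --- providers and teams -------------------------------------------------
  prov <- with_stream(seeds[11], {
    am <- config$adherence_model
    pid <- sprintf("A%04d", seq_len(config$n_providers))
    primary <- sample(names(config$team_mix), config$n_providers, TRUE,
      prob = config$team_mix
    )
    kappa <- am$provider_concentration
    tp <- am$team_propensity
    propensity <- numeric(config$n_providers)
    for (k in seq_len(config$n_providers)) {
      mu <- tp[[primary[k]]]
      if (primary[k] == "solo_attending" && isTRUE(am$solo_bimodal) &&
        is.finite(kappa)) {
        cm <- am$solo_component_means
        wlow <- (cm[2] - mu) / (cm[2] - cm[1])
        wlow <- min(1, max(0, wlow))
        mu <- if (stats::runif(1) < wlow) cm[1] else cm[2]
      }
      propensity[k] <- if (is.finite(kappa)) {
        stats::rbeta(1, mu * kappa, (1 - mu) * kappa)
      } else {
        mu
      }
    }
    assigned <- sample.int(config$n_providers, n, TRUE)
    keep <- rbern(n, config$provider_team_consistency)
    team <- ifelse(
      keep, primary[assigned],
      sample(names(config$team_mix), n, TRUE, prob = config$team_mix)
    )
    list(
      providers = tibble::tibble(
        attending_id = pid, primary_team = primary, propensity = propensity
      ),
      attending_id = pid[assigned],
      propensity = propensity[assigned],
      team = team
    )
  })
  crna <- prov$team %in% c("full_team", "attending_crna")
  resident <- prov$team %in% c("full_team", "attending_resident")

  # --- ledger truths -------------------------------------------------------
  crit_ids <- criterion_definitions()$criterion_id
  majors <- crit_ids[criterion_definitions()$tier == "major"]
  minors <- crit_ids[criterion_definitions()$tier == "minor"]
  majors_true <- Reduce(`+`, truth[majors])
  minors_true <- Reduce(`+`, truth[minors])
  included_true <- majors_true >= 1 | minors_true >= 2

  excl_true <- cbind(
    age_lt_18 = demo$minor,
    pregnant_lactating = excl$pregnant,
    neuromuscular_disease = excl$neuro,
    gfr_lt_30 = excl$gfr_low,
    sugammadex_allergy = excl$allergy_sug,
    planned_postop_intubation = excl$planned_tube,
    direct_icu_admission = excl$disposition == "icu_direct",
    non_intubated = excl$non_intub,
    emergency = excl$emergency
  )
  excluded_true <- rowSums(excl_true) > 0
  # at alert time, late-documented patient-level exclusions are invisible
  visible <- excl_true
  late_cols <- c(
    "pregnant_lactating", "neuromuscular_disease", "gfr_lt_30",
    "sugammadex_allergy"
  )
  visible[, late_cols] <- visible[, late_cols] & !excl$late
  excluded_visible <- rowSums(visible) > 0

  hour_ok <- function(t) {
    s <- sec_of_day(t)
    s >= availability$open_sec & s < availability$close_sec
  }
  expected_alert <- included_true & !excluded_visible &
    sched$site %in% availability$eligible_sites &
    (hour_ok(start - availability$preop_poll_offset_hours * 3600) |
      hour_ok(start + availability$intraop_poll_offset_min * 60))

  # --- provider response stream --------------------------------------------
  resp <- with_stream(seeds[12], {
    am <- config$adherence_model
    dp <- config$delay_probabilities
    delay_patient <- rbern(n, dp[["patient"]])
    delay_scheduling <- rbern(n, dp[["scheduling"]])
    delay_staff <- rbern(n, dp[["staff"]])
    rocu <- rbern(n, config$rocuronium_probability)
    eff <- am$covariate_log_odds
    age_dec <- as.numeric(start_date - demo$birth_date) / 365.25 / 10
    lp <- stats::qlogis(pmin(0.999, pmax(0.001, prov$propensity))) +
      eff[["long_surgery"]] * truth$long_surgery +
      eff[["delay_patient"]] * delay_patient +
      eff[["delay_scheduling"]] * delay_scheduling +
      eff[["delay_staff"]] * delay_staff +
      eff[["low_hemoglobin"]] * truth$low_hemoglobin +
      eff[["low_preop_spo2"]] * truth$low_preop_spo2 +
      eff[["bmi_gt_40"]] * truth$bmi_gt_40 +
      eff[["age_per_decade"]] * (age_dec - 6)
    p_enroll <- stats::plogis(lp)
    intended <- rbern(n, p_enroll)
    enrolled <- expected_alert & intended
    bypass_stock <- expected_alert & !intended &
      rbern(n, am$stock_bypass_share)
    # unalerted background practice
    bg_stock <- !expected_alert & rocu & rbern(n, 0.3)
    neo <- rocu & !enrolled & !bypass_stock & !bg_stock & rbern(n, 0.6)
    list(
      delay_patient = delay_patient, delay_scheduling = delay_scheduling,
      delay_staff = delay_staff, rocu = rocu, p_enroll = p_enroll,
      intended = intended, enrolled = enrolled,
      stock = bypass_stock | bg_stock, neo = neo,
      pacu_los = round(stats::rlnorm(n, log(75), 0.45)),
      min_spo2 = round(stats::runif(n, 88, 99), 1),
      reintubation = rbern(n, 0.005),
      death = rbern(n, 0.001)
    )
  })

  # --- assemble tables -----------------------------------------------------
  patients <- tibble::tibble(
    patient_id = patient_id,
    birth_date = demo$birth_date,
    sex = demo$sex,
    pregnant_or_lactating = excl$pregnant,
    allergies = excl$allergies,
    preop_copd = realz$preop_copd,
    preop_supplemental_o2 = realz$preop_o2,
    preop_lung_transplant = realz$preop_tx,
    preop_recent_uri = realz$preop_uri,
    preop_sleep_apnea = realz$preop_apnea,
    neuromuscular_disease = excl$neuro,
    gfr_latest = excl$gfr,
    vent_hours_pre_admission = airway_real$vent,
    tracheostomy_pre_admission = airway_real$trach,
    prior_max_intubation_attempts = airway_real$attempts,
    exclusion_documented_at = excl$doc_at
  )

  noise_dx <- with_stream(seeds[13], {
    idx <- which(rbern(n, config$noise_rate))
    tibble::tibble(
      patient_id = patient_id[idx],
      icd10 = sample(.noise_codes, length(idx), TRUE),
      onset_date = start_date[idx] - sample(10L:2000L, length(idx), TRUE)
    )
  })
  diagnoses <- dplyr::bind_rows(c(diag_rows, list(noise = noise_dx)))
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$onset_date,
    diagnoses$icd10
  ), ]

  labs <- dplyr::bind_rows(lab_rows)
  labs <- labs[order(labs$patient_id, labs$collected_at), ]
  vitals <- dplyr::bind_rows(vital_rows)
  vitals <- vitals[order(vitals$patient_id, vitals$observed_at), ]
  bmi_obs <- dplyr::bind_rows(bmi_rows)
  bmi_obs <- bmi_obs[order(bmi_obs$patient_id, bmi_obs$observed_at), ]

  pacu_stay <- excl$disposition %in% c("pacu", "floor")
  cases <- tibble::tibble(
    case_id = case_id,
    patient_id = patient_id,
    site = sched$site,
    scheduled_start = start,
    scheduled_duration_min = case_real$duration,
    service = case_real$service,
    procedure_name = case_real$proc_name,
    cpt_codes = case_real$cpt,
    emergency = excl$emergency,
    airway_plan = ifelse(excl$non_intub, "non_intubated", "intubated_general"),
    planned_postop_intubation = excl$planned_tube,
    attending_id = prov$attending_id,
    crna_present = crna,
    resident_present = resident,
    delay_patient = resp$delay_patient,
    delay_scheduling = resp$delay_scheduling,
    delay_staff = resp$delay_staff,
    disposition = excl$disposition,
    unexpected_icu_transfer = excl$disposition == "icu_unplanned_transfer",
    reintubation = resp$reintubation,
    pacu_los_min = ifelse(pacu_stay, resp$pacu_los, NA_real_),
    min_spo2 = resp$min_spo2,
    death = resp$death
  )

  med_time <- start + case_real$duration * 60 * 0.8
  meds <- dplyr::bind_rows(
    tibble::tibble(
      case_id = case_id[resp$rocu],
      drug = "rocuronium", source = "na",
      administered_at = start[resp$rocu] + 900,
      ordered_via_bpa = FALSE
    ),
    tibble::tibble(
      case_id = case_id[resp$enrolled],
      drug = "sugammadex", source = "study_pathway",
      administered_at = med_time[resp$enrolled],
      ordered_via_bpa = TRUE
    ),
    tibble::tibble(
      case_id = case_id[resp$stock],
      drug = "sugammadex", source = "standard_stock",
      administered_at = med_time[resp$stock],
      ordered_via_bpa = FALSE
    ),
    tibble::tibble(
      case_id = case_id[resp$neo],
      drug = "neostigmine", source = "standard_stock",
      administered_at = med_time[resp$neo],
      ordered_via_bpa = FALSE
    )
  )
  meds <- meds[order(meds$case_id, meds$administered_at, meds$drug), ]

  data <- ehr_dataset(
    patients = patients, diagnoses = diagnoses, labs = labs, vitals = vitals,
    bmi_observations = bmi_obs, cases = cases, meds = meds
  )

  ledger <- tibble::tibble(case_id = case_id, patient_id = patient_id)
  for (id in crit_ids) ledger[[paste0("true_", id)]] <- truth[[id]]
  ledger$majors_true <- as.integer(majors_true)
  ledger$minors_true <- as.integer(minors_true)
  ledger$included_true <- included_true
  for (id in colnames(excl_true)) {
    ledger[[paste0("true_excl_", id)]] <- excl_true[, id]
  }
  ledger$excluded_true <- excluded_true
  ledger$excluded_visible_at_alert <- excluded_visible
  ledger$expected_alert <- expected_alert
  ledger$team <- prov$team
  ledger$attending_id <- prov$attending_id
  ledger$propensity <- prov$propensity
  ledger$p_enroll <- resp$p_enroll
  ledger$intended_enroll <- resp$intended
  ledger$study_drug_given <- resp$enrolled
  ledger$rocuronium_given <- resp$rocu
  ledger$disposition <- excl$disposition

  structure(
    list(
      data = data, ledger = ledger, providers = prov$providers,
      config = config
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d patients (seed %d): %d rule-eligible, %d expected alerts\n",
    x$config$n_patients, x$config$seed,
    sum(x$ledger$included_true & !x$ledger$excluded_true),
    sum(x$ledger$expected_alert)
  ))
  invisible(x)
}

#' Write a generated cohort as a fixture directory
#'
#' Emits the standard dataset tables plus `ledger.csv` and the generating
#' configuration (`sim_config.yaml`, seed included) so the fixture can be
#' regenerated and compared byte-for-byte.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory.
#' @param format Table format, `"csv"` or `"jsonl"`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir, format = "csv") {
  write_dataset(cohort$data, dir, format = format)
  readr::write_csv(cohort$ledger, file.path(dir, "ledger.csv"), na = "")
  # yaml drops names of atomic vectors; emit named vectors as maps
  mapify <- function(x) {
    if (is.list(x)) {
      lapply(x, mapify)
    } else if (!is.null(names(x)) && length(x) > 1) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(mapify(unclass(cohort$config)), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Reconstruct a sim_config from a fixture's YAML
#'
#' @param path Path to a `sim_config.yaml` written by [write_fixture()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  to_named <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  am <- raw$adherence_model
  sim_config(
    n_patients = raw$n_patients, seed = raw$seed,
    first_day = raw$first_day, last_day = raw$last_day,
    criterion_prevalences = to_named(raw$criterion_prevalences),
    exclusion_prevalences = to_named(raw$exclusion_prevalences),
    late_documentation_prob = raw$late_documentation_prob,
    boundary_negative_rate = raw$boundary_negative_rate,
    site_mix = to_named(raw$site_mix),
    team_mix = to_named(raw$team_mix),
    start_hour_weights = to_named(raw$start_hour_weights),
    n_providers = raw$n_providers,
    provider_team_consistency = raw$provider_team_consistency,
    delay_probabilities = to_named(raw$delay_probabilities),
    disposition_model = to_named(raw$disposition_model),
    rocuronium_probability = raw$rocuronium_probability,
    adherence_model = list(
      team_propensity = to_named(am$team_propensity),
      provider_concentration = am$provider_concentration,
      solo_bimodal = am$solo_bimodal,
      solo_component_means = to_named(am$solo_component_means),
      covariate_log_odds = to_named(am$covariate_log_odds),
      stock_bypass_share = am$stock_bypass_share
    ),
    noise_rate = raw$noise_rate
  )
}
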
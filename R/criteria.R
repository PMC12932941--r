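# Rule engine for the respiratory-risk inclusion phenotype: 6 major and
# 5 minor inclusion criteria plus 7+2 exclusion flags, evaluated for each
# (patient, case) pair from timestamped facts. Only facts visible at `as_of`
# are considered; criterion windows are anchored at the scheduled case start.

#' Screening configuration
#'
#' Loads the externalized criterion definitions (thresholds, lookback
#' windows, surgical-site token lists, head-and-neck rule variant) and the
#' ICD/CPT code sets. Both resources are shipped as versioned YAML so audits
#' can diff them against the source criterion table.
#'
#' @param criteria_path Path to a criteria YAML; default: shipped resource.
#' @param code_sets_path Path to a code-set YAML; default: shipped resource.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(criteria_path = NULL, code_sets_path = NULL) {
  if (is.null(criteria_path)) {
    criteria_path <- system.file("extdata", "criteria.yaml",
      package = "periscreen"
    )
  }
  cfg <- yaml::read_yaml(criteria_path)
  sets <- load_code_sets(code_sets_path)
  structure(
    list(
      version = cfg$version,
      rule = cfg$inclusion_rule,
      windows = cfg$windows,
      thresholds = cfg$thresholds,
      exclusion_thresholds = cfg$exclusion_thresholds,
      site = cfg$surgical_site,
      sets = sets
    ),
    class = "screening_config"
  )
}

#' Criterion catalogue
#'
#' @return Tibble with `criterion_id`, `tier` (major/minor) and a label for
#'   each of the 11 inclusion criteria.
#' @export
criterion_definitions <- function() {
  tibble::tribble(
    ~criterion_id, ~tier, ~label,
    "lung_disease", "major", "History of obstructive / restrictive lung disease",
    "acute_respiratory_infection", "major", "Acute respiratory infection within 1 month of surgery",
    "obstructive_sleep_apnea", "major", "Obstructive sleep apnea",
    "low_preop_spo2", "major", "Average preoperative SpO2 < 95% in the prior 12 h",
    "airway_pathology", "major", "Previous history of airway pathology",
    "bmi_gt_40", "major", "BMI > 40 on admission",
    "multiple_intubation_attempts", "minor", "More than 1 intubation attempt in a single prior case",
    "long_surgery", "minor", "Surgery scheduled for more than 2 hours",
    "surgical_site", "minor", "Upper abdominal / intrathoracic / head and neck surgery",
    "bmi_gt_35", "minor", "BMI > 35 on admission",
    "low_hemoglobin", "minor", "Hemoglobin < 10 g/dL in the past 6 months"
  )
}

exclusion_ids <- function() {
  c(
    "age_lt_18", "pregnant_lactating", "neuromuscular_disease", "gfr_lt_30",
    "sugammadex_allergy", "planned_postop_intubation", "direct_icu_admission",
    "non_intubated", "emergency"
  )
}

contains_any <- function(x, tokens) {
  lx <- tolower(x)
  hit <- rep(FALSE, length(x))
  for (tok in tokens) {
    hit <- hit | grepl(tolower(tok), lx, fixed = TRUE)
  }
  hit
}

# per-case as_of: NULL -> scheduled_start; "post_hoc" -> all facts visible;
# POSIXct scalar or vector -> as given
resolve_as_of <- function(cases, as_of) {
  if (is.null(as_of)) {
    return(cases$scheduled_start)
  }
  if (identical(as_of, "post_hoc")) {
    return(as.POSIXct("9999-12-31 00:00:00", tz = "UTC") +
      numeric(nrow(cases)))
  }
  stopifnot(inherits(as_of, "POSIXct"))
  if (length(as_of) == 1L) {
    return(rep(as_of, nrow(cases)))
  }
  stopifnot(length(as_of) == nrow(cases))
  as_of
}

# case-keyed flag: TRUE for case_ids present in `hits`
flag_in <- function(case_id, hits) case_id %in% hits

#' Screen every case in a dataset for trial eligibility
#'
#' Evaluates the 6 major and 5 minor inclusion criteria and all exclusion
#' flags for each surgical case, using only facts whose timestamps are at or
#' before `as_of` (default: the case's scheduled start). Inclusion follows
#' the phenotype rule: at least one major criterion or at least two minor
#' criteria. The result is one row per case with per-criterion booleans,
#' criterion counts, the inclusion verdict, per-exclusion booleans and the
#' overall `eligible` flag (included and not excluded). The verdict is
#' invariant to the storage order of patient facts.
#'
#' @param data An `ehr_dataset`.
#' @param config A [screening_config()].
#' @param as_of `NULL` (scheduled start), the string `"post_hoc"` (consider
#'   every fact regardless of documentation time), or a POSIXct scalar /
#'   per-case vector.
#' @return A tibble of class `eligibility_table`.
#' @export
screen_cases <- function(data, config = screening_config(), as_of = NULL) {
  stopifnot(inherits(data, "ehr_dataset"), inherits(config, "screening_config"))
  cases <- data$cases
  crit <- criterion_definitions()
  if (!nrow(cases)) {
    out <- tibble::tibble(case_id = character(), patient_id = character())
    for (id in crit$criterion_id) out[[id]] <- logical()
    out$majors_met <- integer()
    out$minors_met <- integer()
    out$included <- logical()
    for (id in exclusion_ids()) out[[paste0("excl_", id)]] <- logical()
    out$excluded_any <- logical()
    out$eligible <- logical()
    return(structure(out, class = c("eligibility_table", class(out))))
  }

  as_of_t <- resolve_as_of(cases, as_of)
  key <- tibble::tibble(
    case_id = cases$case_id,
    patient_id = cases$patient_id,
    start = cases$scheduled_start,
    start_date = as.Date(cases$scheduled_start, tz = "UTC"),
    as_of = as_of_t,
    as_of_date = as.Date(as_of_t, tz = "UTC")
  )
  w <- config$windows
  th <- config$thresholds

  # --- diagnosis-driven criteria -------------------------------------------
  diag <- data$diagnoses
  diag_hits <- function(set, window_days = NULL) {
    if (!nrow(diag)) {
      return(character())
    }
    d <- diag[code_matches(diag$icd10, set), , drop = FALSE]
    if (!nrow(d)) {
      return(character())
    }
    j <- dplyr::inner_join(d, key,
      by = "patient_id", relationship = "many-to-many"
    )
    j <- j[j$onset_date <= j$as_of_date & j$onset_date <= j$start_date, ,
      drop = FALSE
    ]
    if (!is.null(window_days)) {
      j <- j[j$onset_date >= j$start_date - window_days, , drop = FALSE]
    }
    unique(j$case_id)
  }
  lung_dx <- diag_hits(config$sets$icd$obstructive_restrictive_lung_disease)
  ari_dx <- diag_hits(config$sets$icd$acute_respiratory_infection,
    window_days = w$acute_infection_days
  )
  osa_dx <- diag_hits(config$sets$icd$obstructive_sleep_apnea)

  p <- data$patients[match(key$patient_id, data$patients$patient_id), ]

  lung <- flag_in(key$case_id, lung_dx) |
    p$preop_copd | p$preop_supplemental_o2 | p$preop_lung_transplant
  ari <- flag_in(key$case_id, ari_dx) | p$preop_recent_uri
  osa <- flag_in(key$case_id, osa_dx) | p$preop_sleep_apnea

  # --- SpO2: mean of samples in (start - 12 h, start], strict < threshold;
  #     false when the window holds no samples -----------------------------
  vit <- data$vitals
  spo2 <- rep(FALSE, nrow(key))
  if (nrow(vit)) {
    v <- vit[vit$kind == "spo2" & is.finite(vit$value), , drop = FALSE]
    if (nrow(v)) {
      j <- dplyr::inner_join(v, key,
        by = "patient_id", relationship = "many-to-many"
      )
      j <- j[j$observed_at > j$start - w$spo2_hours * 3600 &
        j$observed_at <= j$start & j$observed_at <= j$as_of, , drop = FALSE]
      if (nrow(j)) {
        means <- tapply(j$value, j$case_id, mean)
        low <- names(means)[means < th$spo2_mean_lt]
        spo2 <- flag_in(key$case_id, low)
      }
    }
  }

  # --- airway history (pre-admission facts on the patient record) ----------
  airway <- (p$vent_hours_pre_admission > th$ventilator_gt_hours) |
    p$tracheostomy_pre_admission
  attempts <- p$prior_max_intubation_attempts > th$intubation_attempts_gt

  # --- admission BMI: latest observation at or before the case start -------
  bmi_latest <- rep(NA_real_, nrow(key))
  bo <- data$bmi_observations
  if (nrow(bo)) {
    j <- dplyr::inner_join(bo, key,
      by = "patient_id", relationship = "many-to-many"
    )
    j <- j[j$observed_at <= j$start & j$observed_at <= j$as_of, , drop = FALSE]
    if (nrow(j)) {
      j <- j[order(j$case_id, j$observed_at), , drop = FALSE]
      last <- j[!duplicated(j$case_id, fromLast = TRUE), c("case_id", "bmi")]
      bmi_latest <- last$bmi[match(key$case_id, last$case_id)]
    }
  }
  bmi40 <- !is.na(bmi_latest) & bmi_latest > th$bmi_major_gt
  bmi35 <- !is.na(bmi_latest) & bmi_latest > th$bmi_minor_gt

  # --- hemoglobin < 10 g/dL within the 183-day lookback --------------------
  labs <- data$labs
  hgb <- rep(FALSE, nrow(key))
  if (nrow(labs)) {
    l <- labs[labs$analyte == "hemoglobin_serum" & is.finite(labs$value), ,
      drop = FALSE
    ]
    if (nrow(l)) {
      j <- dplyr::inner_join(l, key,
        by = "patient_id", relationship = "many-to-many"
      )
      j <- j[j$collected_at >= j$start - w$hemoglobin_days * 86400 &
        j$collected_at <= j$start & j$collected_at <= j$as_of &
        j$value < th$hemoglobin_lt, , drop = FALSE]
      hgb <- flag_in(key$case_id, unique(j$case_id))
    }
  }

  long <- cases$scheduled_duration_min > th$duration_gt_min
  site <- surgical_site_met(cases, config)

  out <- tibble::tibble(
    case_id = key$case_id,
    patient_id = key$patient_id,
    lung_disease = lung,
    acute_respiratory_infection = ari,
    obstructive_sleep_apnea = osa,
    low_preop_spo2 = spo2,
    airway_pathology = airway,
    bmi_gt_40 = bmi40,
    multiple_intubation_attempts = attempts,
    long_surgery = long,
    surgical_site = site,
    bmi_gt_35 = bmi35,
    low_hemoglobin = hgb
  )
  majors <- crit$criterion_id[crit$tier == "major"]
  minors <- crit$criterion_id[crit$tier == "minor"]
  out$majors_met <- as.integer(rowSums(as.matrix(out[majors])))
  out$minors_met <- as.integer(rowSums(as.matrix(out[minors])))
  out$included <- out$majors_met >= config$rule$majors_required |
    out$minors_met >= config$rule$minors_required

  ex <- screen_exclusions(data, config, as_of = as_of)
  for (id in exclusion_ids()) out[[paste0("excl_", id)]] <- ex[[id]]
  out$excluded_any <- ex$excluded_any
  out$eligible <- out$included & !out$excluded_any
  structure(out, class = c("eligibility_table", class(out)))
}

# surgical-site minor criterion (case fields only)
surgical_site_met <- function(cases, config) {
  sc <- config$site
  name <- cases$procedure_name
  service <- cases$service
  required <- service != sc$excluded_service &
    !contains_any(name, sc$excluded_name_token)
  qual <- rep(FALSE, nrow(cases))
  for (svc in names(sc$service_tokens)) {
    qual <- qual |
      (service == svc & contains_any(name, unlist(sc$service_tokens[[svc]])))
  }
  hn_tok <- unlist(sc$head_neck_tokens)
  hn_hits <- vapply(
    hn_tok,
    function(tok) contains_any(name, tok),
    logical(nrow(cases))
  )
  hn_hits <- matrix(hn_hits, nrow = nrow(cases))
  disq <- if (identical(sc$head_neck_rule, "either")) {
    rowSums(hn_hits) >= 1
  } else {
    rowSums(hn_hits) == length(hn_tok)
  }
  qual <- qual | (service == sc$head_neck_service & !disq)
  cpt_set <- config$sets$cpt[[sc$cpt_set]]
  cpt_tokens <- vapply(cpt_set$parsed, function(t) t$root, character(1))
  cpt_hit <- vapply(
    split_list_col(cases$cpt_codes),
    function(codes) any(codes %in% cpt_tokens),
    logical(1)
  )
  required & (qual | cpt_hit)
}

#' Evaluate exclusion criteria for every case
#'
#' Flags the study exclusions for each case: age under 18 full years at the
#' scheduled start, pregnancy/lactation, pre-existing neuromuscular disease,
#' latest GFR strictly below 30 mL/min/1.73m2, documented sugammadex allergy,
#' planned postoperative intubation, planned direct ICU admission,
#' non-intubated airway plan, and emergency surgery. Patient-level exclusion
#' attributes (pregnancy, neuromuscular disease, allergy, GFR) count only
#' when their documentation timestamp (`exclusion_documented_at`, `NA` =
#' always known) is at or before `as_of`, which is how documentation latency
#' can make an alert-time screen miss a true exclusion. An unplanned ICU
#' transfer is not an exclusion: it cannot be known at evaluation time.
#' Absent GFR never excludes.
#'
#' @inheritParams screen_cases
#' @return Tibble with `case_id`, one logical column per exclusion flag and
#'   `excluded_any`.
#' @export
screen_exclusions <- function(data, config = screening_config(),
                              as_of = NULL) {
  cases <- data$cases
  et <- config$exclusion_thresholds
  as_of_t <- resolve_as_of(cases, as_of)
  p <- data$patients[match(cases$patient_id, data$patients$patient_id), ]

  start_date <- as.Date(cases$scheduled_start, tz = "UTC")
  age <- age_years(p$birth_date, start_date)
  doc_visible <- is.na(p$exclusion_documented_at) |
    p$exclusion_documented_at <= as_of_t
  allergy <- vapply(
    split_list_col(p$allergies),
    function(a) "sugammadex" %in% tolower(trimws(a)),
    logical(1)
  )

  out <- tibble::tibble(
    case_id = cases$case_id,
    age_lt_18 = age < et$age_lt_years,
    pregnant_lactating = doc_visible & p$pregnant_or_lactating,
    neuromuscular_disease = doc_visible & p$neuromuscular_disease,
    gfr_lt_30 = doc_visible & !is.na(p$gfr_latest) & p$gfr_latest < et$gfr_lt,
    sugammadex_allergy = doc_visible & allergy,
    planned_postop_intubation = cases$planned_postop_intubation,
    direct_icu_admission = cases$disposition == "icu_direct",
    non_intubated = cases$airway_plan == "non_intubated",
    emergency = cases$emergency
  )
  out$excluded_any <- Reduce(`|`, out[exclusion_ids()])
  out
}

# full years of age at `at` (Date); the 18th birthday itself is age 18
age_years <- function(birth, at) {
  by <- as.integer(format(birth, "%Y"))
  ay <- as.integer(format(at, "%Y"))
  raw <- ay - by
  before_bday <- format(at, "%m%d") < format(birth, "%m%d")
  raw - as.integer(before_bday)
}

#' Evaluate a single case in detail
#'
#' Runs the same rule engine as [screen_cases()] on one case and returns an
#' `eligibility_decision` with per-criterion results, the supporting evidence
#' for every met criterion (the triggering diagnosis, lab, vital-window
#' summary or case field), criterion counts, the inclusion verdict and the
#' set of exclusion flags.
#'
#' @param data An `ehr_dataset`.
#' @param case_id Case identifier.
#' @param config A [screening_config()].
#' @param as_of As in [screen_cases()].
#' @return An object of class `eligibility_decision`.
#' @export
evaluate_case <- function(data, case_id, config = screening_config(),
                          as_of = NULL) {
  i <- match(case_id, data$cases$case_id)
  if (is.na(i)) stop("unknown case_id: '", case_id, "'", call. = FALSE)
  sub <- ehr_dataset(
    patients = data$patients,
    diagnoses = data$diagnoses, labs = data$labs, vitals = data$vitals,
    bmi_observations = data$bmi_observations,
    cases = data$cases[i, , drop = FALSE],
    meds = data$meds[data$meds$case_id == case_id, , drop = FALSE],
    validate = FALSE
  )
  row <- screen_cases(sub, config, as_of = as_of)
  crit <- criterion_definitions()
  ev <- gather_evidence(sub, config, as_of)
  results <- tibble::tibble(
    criterion_id = crit$criterion_id,
    tier = crit$tier,
    met = vapply(crit$criterion_id, function(id) row[[id]], logical(1)),
    evidence = lapply(crit$criterion_id, function(id) {
      if (row[[id]]) ev[[id]] else character()
    })
  )
  exfl <- exclusion_ids()
  exset <- exfl[vapply(
    exfl, function(id) row[[paste0("excl_", id)]], logical(1)
  )]
  structure(
    list(
      case_id = case_id,
      patient_id = row$patient_id,
      evaluated_at = resolve_as_of(sub$cases, as_of),
      criterion_results = results,
      majors_met = row$majors_met,
      minors_met = row$minors_met,
      included = row$included,
      exclusions = exset,
      eligible = row$eligible
    ),
    class = "eligibility_decision"
  )
}

#' @export
print.eligibility_decision <- function(x, ...) {
  cat(sprintf(
    "<eligibility_decision> case %s: %s (%d major, %d minor)\n",
    x$case_id, if (x$included) "INCLUDED" else "not included",
    x$majors_met, x$minors_met
  ))
  met <- x$criterion_results[x$criterion_results$met, ]
  if (nrow(met)) {
    for (k in seq_len(nrow(met))) {
      cat(sprintf(
        "  [%s] %s: %s\n", met$tier[k], met$criterion_id[k],
        paste(met$evidence[[k]], collapse = "; ")
      ))
    }
  }
  if (length(x$exclusions)) {
    cat("  exclusions:", paste(x$exclusions, collapse = ", "), "\n")
  }
  invisible(x)
}

# human-readable evidence strings for one-case data (met criteria only)
gather_evidence <- function(sub, config, as_of) {
  case <- sub$cases[1, ]
  p <- sub$patients[match(case$patient_id, sub$patients$patient_id), ]
  as_of_t <- resolve_as_of(sub$cases, as_of)
  start <- case$scheduled_start
  start_date <- as.Date(start, tz = "UTC")
  w <- config$windows
  diag <- sub$diagnoses[sub$diagnoses$patient_id == case$patient_id &
    sub$diagnoses$onset_date <= as.Date(as_of_t, tz = "UTC") &
    sub$diagnoses$onset_date <= start_date, , drop = FALSE]
  dx_ev <- function(set, window_days = NULL, flags = character()) {
    d <- diag[code_matches(diag$icd10, set), , drop = FALSE]
    if (!is.null(window_days)) {
      d <- d[d$onset_date >= start_date - window_days, , drop = FALSE]
    }
    c(
      sprintf("diagnosis %s (onset %s)", d$icd10, d$onset_date),
      sprintf("preop evaluation flag: %s", flags)
    )
  }
  flags_of <- function(...) {
    nm <- c(...)
    nm[vapply(nm, function(f) isTRUE(p[[paste0("preop_", f)]]), logical(1))]
  }
  vit <- sub$vitals[sub$vitals$patient_id == case$patient_id &
    sub$vitals$kind == "spo2" &
    sub$vitals$observed_at > start - w$spo2_hours * 3600 &
    sub$vitals$observed_at <= start &
    sub$vitals$observed_at <= as_of_t, , drop = FALSE]
  bo <- sub$bmi_observations[
    sub$bmi_observations$patient_id == case$patient_id &
      sub$bmi_observations$observed_at <= start &
      sub$bmi_observations$observed_at <= as_of_t, ,
    drop = FALSE
  ]
  bmi_ev <- if (nrow(bo)) {
    bo <- bo[order(bo$observed_at), ]
    sprintf(
      "latest BMI %.1f kg/m2 (%s)", bo$bmi[nrow(bo)],
      fmt_dttm(bo$observed_at[nrow(bo)])
    )
  } else {
    character()
  }
  labs <- sub$labs[sub$labs$patient_id == case$patient_id &
    sub$labs$analyte == "hemoglobin_serum" &
    sub$labs$collected_at >= start - w$hemoglobin_days * 86400 &
    sub$labs$collected_at <= start &
    sub$labs$collected_at <= as_of_t &
    sub$labs$value < config$thresholds$hemoglobin_lt, , drop = FALSE]
  list(
    lung_disease = dx_ev(
      config$sets$icd$obstructive_restrictive_lung_disease,
      flags = flags_of("copd", "supplemental_o2", "lung_transplant")
    ),
    acute_respiratory_infection = dx_ev(
      config$sets$icd$acute_respiratory_infection,
      window_days = w$acute_infection_days, flags = flags_of("recent_uri")
    ),
    obstructive_sleep_apnea = dx_ev(
      config$sets$icd$obstructive_sleep_apnea,
      flags = flags_of("sleep_apnea")
    ),
    low_preop_spo2 = if (nrow(vit)) {
      sprintf(
        "mean SpO2 %.1f%% over %d sample(s) in the 12 h window",
        mean(vit$value), nrow(vit)
      )
    } else {
      character()
    },
    airway_pathology = c(
      if (isTRUE(p$vent_hours_pre_admission >
        config$thresholds$ventilator_gt_hours)) {
        sprintf("%.0f h on mechanical ventilator", p$vent_hours_pre_admission)
      },
      if (isTRUE(p$tracheostomy_pre_admission)) "pre-admission tracheostomy"
    ),
    bmi_gt_40 = bmi_ev,
    bmi_gt_35 = bmi_ev,
    multiple_intubation_attempts = sprintf(
      "%d intubation attempts in a prior case",
      p$prior_max_intubation_attempts
    ),
    long_surgery = sprintf(
      "scheduled for %.0f min", case$scheduled_duration_min
    ),
    surgical_site = sprintf(
      "service '%s', procedure '%s'%s", case$service, case$procedure_name,
      if (nzchar(case$cpt_codes)) paste0(", CPT ", case$cpt_codes) else ""
    ),
    low_hemoglobin = sprintf(
      "hemoglobin %.1f g/dL (%s)", labs$value, fmt_dttm(labs$collected_at)
    )
  )
}
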
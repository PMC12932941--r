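# Deliberately naive, independent re-implementation of the eligibility
# phenotype, used as an oracle. It re-reads every fact per case with plain
# base-R loops and spells out each rule from scratch; it shares no code with
# the engine beyond the shipped YAML definitions it is checking against.

oracle_norm <- function(code) {
  out <- character(length(code))
  for (i in seq_along(code)) {
    chars <- strsplit(trimws(code[i]), "")[[1]]
    chars <- chars[chars != "."]
    out[i] <- paste(toupper(chars), collapse = "")
  }
  out
}

# interval-membership oracle for a single token. Ranges are mapped to real
# intervals: a code's digit suffix s denotes the point 0.s, and a range
# lo-hi covers [0.s_lo, 0.s_hi + 10^-len(s_hi)), i.e. hi and all its
# descendants. This arithmetic route is independent of the engine's padded
# string comparison.
oracle_token_match <- function(code, token) {
  code <- oracle_norm(code)
  if (grepl("-", token, fixed = TRUE)) {
    ends <- oracle_norm(strsplit(token, "-", fixed = TRUE)[[1]])
    lo <- ends[1]
    hi <- ends[2]
    if (substr(code, 1, 3) != substr(lo, 1, 3)) {
      return(FALSE)
    }
    sfx <- function(x) substr(x, 4, nchar(x))
    stopifnot(grepl("^[0-9]*$", c(sfx(code), sfx(lo), sfx(hi))))
    w <- max(nchar(sfx(code)), nchar(sfx(lo)), nchar(sfx(hi)))
    scaled <- function(s) {
      if (!nzchar(s)) 0 else as.numeric(s) * 10^(w - nchar(s))
    }
    v <- scaled(sfx(code))
    upper <- if (nzchar(sfx(hi))) {
      (as.numeric(sfx(hi)) + 1) * 10^(w - nchar(sfx(hi)))
    } else {
      10^w
    }
    return(v >= scaled(sfx(lo)) && v < upper)
  }
  root <- oracle_norm(sub("\\.[xX]$", "", token))
  code == root || substr(code, 1, nchar(root)) == root
}

oracle_set_match <- function(code, tokens) {
  for (tok in tokens) {
    if (oracle_token_match(code, tok)) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_code_sets <- function() {
  raw <- yaml::read_yaml(
    system.file("extdata", "code_sets.yaml", package = "periscreen")
  )
  lapply(raw$code_sets, function(x) unlist(x$tokens))
}

# full per-case re-evaluation: one case at a time, base R only
naive_screen_one <- function(data, case_idx) {
  case <- as.list(data$cases[case_idx, ])
  pid <- case$patient_id
  p <- as.list(data$patients[data$patients$patient_id == pid, ])
  start <- case$scheduled_start
  start_date <- as.Date(start, tz = "UTC")
  sets <- oracle_code_sets()

  dx <- data$diagnoses[data$diagnoses$patient_id == pid, ]
  dx <- dx[dx$onset_date <= start_date, , drop = FALSE]
  any_dx <- function(tokens, min_date = NULL) {
    for (i in seq_len(nrow(dx))) {
      if (!is.null(min_date) && dx$onset_date[i] < min_date) next
      if (oracle_set_match(dx$icd10[i], tokens)) {
        return(TRUE)
      }
    }
    FALSE
  }

  lung <- any_dx(sets$obstructive_restrictive_lung_disease) ||
    isTRUE(p$preop_copd) || isTRUE(p$preop_supplemental_o2) ||
    isTRUE(p$preop_lung_transplant)
  ari <- any_dx(sets$acute_respiratory_infection, start_date - 30) ||
    isTRUE(p$preop_recent_uri)
  osa <- any_dx(sets$obstructive_sleep_apnea) || isTRUE(p$preop_sleep_apnea)

  v <- data$vitals[data$vitals$patient_id == pid & data$vitals$kind == "spo2", ]
  in_win <- v$observed_at > (start - 12 * 3600) & v$observed_at <= start
  spo2 <- if (any(in_win)) mean(v$value[in_win]) < 95 else FALSE

  airway <- p$vent_hours_pre_admission > 24 ||
    isTRUE(p$tracheostomy_pre_admission)
  attempts <- p$prior_max_intubation_attempts > 1

  b <- data$bmi_observations[data$bmi_observations$patient_id == pid, ]
  b <- b[b$observed_at <= start, , drop = FALSE]
  bmi <- if (nrow(b)) b$bmi[order(b$observed_at)][nrow(b)] else NA_real_
  bmi40 <- !is.na(bmi) && bmi > 40
  bmi35 <- !is.na(bmi) && bmi > 35

  l <- data$labs[data$labs$patient_id == pid &
    data$labs$analyte == "hemoglobin_serum", ]
  hgb <- FALSE
  for (i in seq_len(nrow(l))) {
    if (l$collected_at[i] >= start - 183 * 86400 &&
      l$collected_at[i] <= start && l$value[i] < 10) {
      hgb <- TRUE
    }
  }

  long <- case$scheduled_duration_min > 120

  nm <- tolower(case$procedure_name)
  has <- function(tok) grepl(tolower(tok), nm, fixed = TRUE)
  site <- FALSE
  if (case$service != "Neurosurgery" && !has("transplant")) {
    if (case$service == "General Surgery" &&
      (has("Gastric") || has("Liver") || has("Pancreas") || has("Hepat") ||
        has("Chole"))) {
      site <- TRUE
    }
    if (case$service == "Thoracic Surgery" &&
      (has("Pulm") || has("Resection") || has("Esoph") || has("VATS") ||
        has("Lobe") || has("Thoracotomy"))) {
      site <- TRUE
    }
    if (case$service == "Head and Neck" && !(has("Mastoid") && has("Tympano"))) {
      site <- TRUE
    }
    cpts <- strsplit(case$cpt_codes, ";", fixed = TRUE)[[1]]
    if (any(cpts %in% c("43775", "47562", "43644", "43774"))) site <- TRUE
  }

  majors <- sum(lung, ari, osa, spo2, airway, bmi40)
  minors <- sum(attempts, long, site, bmi35, hgb)

  # exclusions, with alert-time documentation gating at as_of = start
  doc_ok <- is.na(p$exclusion_documented_at) ||
    p$exclusion_documented_at <= start
  years <- as.integer(format(start_date, "%Y")) -
    as.integer(format(p$birth_date, "%Y"))
  if (format(start_date, "%m%d") < format(p$birth_date, "%m%d")) {
    years <- years - 1
  }
  allergy <- "sugammadex" %in%
    tolower(strsplit(p$allergies, ";", fixed = TRUE)[[1]])
  excl <- c(
    years < 18,
    doc_ok && isTRUE(p$pregnant_or_lactating),
    doc_ok && isTRUE(p$neuromuscular_disease),
    doc_ok && !is.na(p$gfr_latest) && p$gfr_latest < 30,
    doc_ok && allergy,
    isTRUE(case$planned_postop_intubation),
    case$disposition == "icu_direct",
    case$airway_plan == "non_intubated",
    isTRUE(case$emergency)
  )

  list(
    case_id = case$case_id,
    majors = majors, minors = minors,
    included = majors >= 1 || minors >= 2,
    excluded = any(excl)
  )
}

naive_screen <- function(data) {
  rows <- lapply(seq_len(nrow(data$cases)), function(i) {
    r <- naive_screen_one(data, i)
    data.frame(
      case_id = r$case_id, majors = r$majors, minors = r$minors,
      included = r$included, excluded = r$excluded
    )
  })
  do.call(rbind, rows)
}
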
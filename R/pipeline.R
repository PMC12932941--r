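# Batch pipeline: simulate -> screen -> alerts -> classify -> report, each
# stage reading the previous stage's artifact, with a run manifest for
# traceability.

#' Assemble the adherent-vs-non-adherent bias table inputs
#'
#' One row per alerted, appropriately allocated case with the variables the
#' bias assessment compares between provider-adherent and non-adherent
#' groups: age, admission BMI, PACU length of stay, minimum oxygen
#' saturation, unexpected ICU transfer and reintubation. Mortality is kept
#' as counts only (a very low-frequency outcome is summarised, not tested).
#'
#' @param data An `ehr_dataset`.
#' @param outcomes Tibble from [classify_cases()].
#' @return Tibble with an `adherent` logical column.
#' @export
bias_frame <- function(data, outcomes) {
  sub <- outcomes[outcomes$status %in% appropriate_statuses(), ]
  ci <- match(sub$case_id, data$cases$case_id)
  cases <- data$cases[ci, ]
  p <- data$patients[match(cases$patient_id, data$patients$patient_id), ]
  bo <- data$bmi_observations
  bmi_latest <- rep(NA_real_, nrow(cases))
  if (nrow(bo)) {
    j <- dplyr::inner_join(
      bo,
      tibble::tibble(
        case_id = cases$case_id, patient_id = cases$patient_id,
        start = cases$scheduled_start
      ),
      by = "patient_id", relationship = "many-to-many"
    )
    j <- j[j$observed_at <= j$start, , drop = FALSE]
    if (nrow(j)) {
      j <- j[order(j$case_id, j$observed_at), ]
      last <- j[!duplicated(j$case_id, fromLast = TRUE), c("case_id", "bmi")]
      bmi_latest <- last$bmi[match(cases$case_id, last$case_id)]
    }
  }
  tibble::tibble(
    case_id = cases$case_id,
    adherent = sub$status == "enrolled",
    age = age_years(p$birth_date, as.Date(cases$scheduled_start, tz = "UTC")),
    bmi = bmi_latest,
    pacu_los_min = cases$pacu_los_min,
    min_spo2 = cases$min_spo2,
    unexpected_icu_transfer = cases$unexpected_icu_transfer,
    reintubation = cases$reintubation,
    death = cases$death
  )
}

default_bias_vars <- function() {
  c(
    age = "continuous_skewed",
    bmi = "continuous_normal",
    pacu_los_min = "continuous_skewed",
    min_spo2 = "continuous_skewed",
    unexpected_icu_transfer = "categorical",
    reintubation = "categorical"
  )
}

#' Build the full analysis report for a classified cohort
#'
#' Computes the cohort funnel, the metric set with CIs, team-stratified
#' adherence, provider box-plot statistics, the bias-comparison table
#' (no multiple-testing adjustment, mirroring a descriptive presentation)
#' and the multivariable adherence model, and writes each as CSV plus a
#' human-readable `report.md` (and a box-plot figure) to `out_dir`.
#'
#' @param data An `ehr_dataset`.
#' @param decisions Eligibility table from [screen_cases()].
#' @param alerts Alert ledger from [run_alerts()].
#' @param outcomes Tibble from [classify_cases()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param write_figure Also render the provider-adherence box plot (PNG).
#' @return List with `funnel`, `metrics`, `team_adherence`, `providers`,
#'   `bias`, `model`, invisibly when writing.
#' @export
build_report <- function(data, decisions, alerts, outcomes, out_dir = NULL,
                         write_figure = TRUE) {
  funnel <- tibble::tibble(
    stage = c("cases", "rule_eligible", "alerted", "appropriate", "enrolled"),
    n = c(
      nrow(data$cases),
      sum(decisions$eligible),
      length(unique(alerts$case_id)),
      sum(outcomes$status %in% appropriate_statuses()),
      sum(outcomes$status == "enrolled")
    )
  )
  metrics <- cohort_metrics(outcomes)
  est_row <- function(name, est) {
    if (is.null(est)) {
      return(NULL)
    }
    tibble::tibble(
      metric = name, numerator = est$numerator,
      denominator = est$denominator, proportion = est$proportion,
      ci_low = est$ci_low, ci_high = est$ci_high, ci_method = est$ci_method
    )
  }
  metric_tbl <- dplyr::bind_rows(
    est_row("allocation_accuracy_pacu", metrics$allocation_accuracy_pacu),
    est_row("allocation_accuracy_all", metrics$allocation_accuracy_all),
    est_row("misallocation_rate", metrics$misallocation_rate),
    est_row("icu_share", metrics$icu_share),
    est_row("adherence_overall", metrics$adherence_overall),
    est_row("adherence_all_alerted", metrics$adherence_all_alerted),
    est_row("rocuronium_share_pacu", metrics$rocuronium_share_pacu)
  )
  team_tbl <- dplyr::bind_rows(lapply(
    names(metrics$adherence_by_team),
    function(tm) est_row(tm, metrics$adherence_by_team[[tm]])
  ))
  dist <- provider_distribution(outcomes)
  bf <- bias_frame(data, outcomes)
  bias <- if (nrow(bf) && length(unique(bf$adherent)) == 2) {
    compare_groups(bf, "adherent", default_bias_vars())
  } else {
    NULL
  }
  deaths <- if (nrow(bf)) {
    tibble::tibble(
      group = c("adherent", "non_adherent"),
      deaths = c(sum(bf$death[bf$adherent]), sum(bf$death[!bf$adherent])),
      n = c(sum(bf$adherent), sum(!bf$adherent))
    )
  } else {
    NULL
  }
  mf <- adherence_model_frame(data, outcomes, decisions)
  model <- if (nrow(mf) >= 50 && length(unique(mf$enrolled)) == 2) {
    # separation/drop diagnostics live in the result's fields
    tryCatch(
      suppressWarnings(fit_adherence_model(mf, covariates = c(
        "team", "delay_patient", "delay_scheduling", "delay_staff",
        "long_surgery", "age_decades", "bmi_gt_40", "low_hemoglobin",
        "low_preop_spo2"
      ))),
      error = function(e) NULL
    )
  } else {
    NULL
  }

  out <- list(
    funnel = funnel, metrics = metrics, metric_table = metric_tbl,
    team_adherence = team_tbl, providers = dist, bias = bias,
    deaths = deaths, model = model
  )
  if (is.null(out_dir)) {
    return(out)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tb, name) {
    if (!is.null(tb)) readr::write_csv(tb, file.path(out_dir, name), na = "")
  }
  wr(funnel, "funnel.csv")
  wr(metric_tbl, "metrics.csv")
  wr(team_tbl, "team_adherence.csv")
  wr(dist$providers, "provider_adherence.csv")
  wr(dist$team_summaries, "provider_team_summaries.csv")
  wr(bias, "bias_comparison.csv")
  wr(deaths, "mortality_counts.csv")
  if (!is.null(model)) wr(model$terms, "adherence_model.csv")
  writeLines(render_report_md(out), file.path(out_dir, "report.md"))
  if (write_figure && nrow(dist$providers)) {
    try(
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, "provider_adherence.png"),
        plot_provider_adherence(dist),
        width = 7, height = 4.5, dpi = 150
      )),
      silent = TRUE
    )
  }
  invisible(out)
}

render_report_md <- function(rep) {
  pct <- function(est) {
    if (is.null(est)) {
      return("n/a")
    }
    sprintf(
      "%.1f%% (%d/%d; 95%% CI %.1f%%-%.1f%%)",
      100 * est$proportion, est$numerator, est$denominator,
      100 * est$ci_low, 100 * est$ci_high
    )
  }
  m <- rep$metrics
  lines <- c(
    "# Cohort screening and adherence report",
    "",
    "## Funnel",
    sprintf("- %s: %d", rep$funnel$stage, rep$funnel$n),
    "",
    "## System performance",
    sprintf("- Allocation accuracy (PACU): %s", pct(m$allocation_accuracy_pacu)),
    sprintf("- Allocation accuracy (all alerts): %s", pct(m$allocation_accuracy_all)),
    sprintf("- Misallocation (exclusion met): %s", pct(m$misallocation_rate)),
    sprintf("- ICU disposition share: %s", pct(m$icu_share)),
    sprintf("- Rocuronium share (appropriate): %s", pct(m$rocuronium_share_pacu)),
    "",
    "## Provider adherence",
    sprintf("- Overall (appropriate denominator): %s", pct(m$adherence_overall)),
    sprintf("- Overall (all alerted denominator): %s", pct(m$adherence_all_alerted))
  )
  for (tm in names(m$adherence_by_team)) {
    lines <- c(lines, sprintf("- %s: %s", tm, pct(m$adherence_by_team[[tm]])))
  }
  if (!is.null(rep$bias)) {
    lines <- c(
      lines, "",
      "## Bias comparison (adherent vs non-adherent; no multiplicity adjustment)",
      sprintf(
        "- %s [%s]: p = %s", rep$bias$variable, rep$bias$test,
        ifelse(rep$bias$skipped, "skipped", sprintf("%.3g", rep$bias$p_value))
      )
    )
  }
  if (!is.null(rep$deaths)) {
    lines <- c(lines, sprintf(
      "- mortality (descriptive): %d/%d adherent vs %d/%d non-adherent",
      rep$deaths$deaths[1], rep$deaths$n[1],
      rep$deaths$deaths[2], rep$deaths$n[2]
    ))
  }
  if (!is.null(rep$model)) {
    t <- rep$model$terms
    lines <- c(
      lines, "",
      sprintf("## Adherence model (n = %d; %s)", rep$model$n_fit, rep$model$subset_rule),
      sprintf(
        "- %s: OR %.2f (95%% CI %.2f-%.2f), p = %.3g",
        t$term, t$odds_ratio, t$ci_low, t$ci_high, t$p_value
      )
    )
  }
  lines
}

#' Run the full offline pipeline
#'
#' Executes simulate -> write -> read -> screen -> alerts -> classify ->
#' report with each stage's output feeding the next, and writes a run
#' manifest (config hash, seed, code-set resource version, stage row counts,
#' timestamps) alongside the artifacts. Any stage failure aborts with a
#' diagnostic naming the stage.
#'
#' @param sim A [sim_config()] describing the cohort to generate.
#' @param out_dir Output directory for artifacts (`dataset/`, `screen/`,
#'   `alerts/`, `classify/`, `report/`, `manifest.json`).
#' @param availability An [availability_config()].
#' @param screening A [screening_config()].
#' @param format Dataset interchange format, `"csv"` or `"jsonl"`.
#' @param write_figure Passed to [build_report()].
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(sim = sim_config(), out_dir = tempfile("periscreen_"),
                         availability = availability_config(),
                         screening = screening_config(),
                         format = "csv", write_figure = TRUE) {
  started <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("simulate", generate_cohort(sim, availability))
  data_dir <- file.path(out_dir, "dataset")
  stage("simulate", write_fixture(cohort, data_dir, format = format))
  data <- stage("read", read_dataset(data_dir, format = format))

  decisions <- stage("screen", screen_cases(data, screening))
  screen_dir <- file.path(out_dir, "screen")
  dir.create(screen_dir, showWarnings = FALSE)
  readr::write_csv(decisions, file.path(screen_dir, "eligibility.csv"), na = "")

  al <- stage("alerts", run_alerts(data, decisions, availability))
  alert_dir <- file.path(out_dir, "alerts")
  dir.create(alert_dir, showWarnings = FALSE)
  readr::write_csv(
    serialize_table(al$alerts, c(fired_at = "dttm")),
    file.path(alert_dir, "alerts.csv"),
    na = ""
  )
  readr::write_csv(
    serialize_table(al$log, c(poll_time = "dttm")),
    file.path(alert_dir, "alert_log.csv"),
    na = ""
  )

  outcomes <- stage("classify", classify_cases(data, al$alerts, screening))
  classify_dir <- file.path(out_dir, "classify")
  dir.create(classify_dir, showWarnings = FALSE)
  readr::write_csv(outcomes, file.path(classify_dir, "outcomes.csv"), na = "")

  report <- stage("report", build_report(
    data, decisions, al$alerts, outcomes,
    out_dir = file.path(out_dir, "report"), write_figure = write_figure
  ))

  manifest <- list(
    command = "pipeline",
    package_version = as.character(utils::packageVersion("periscreen")),
    config_hash = rlang::hash(unclass(sim)),
    seed = sim$seed,
    code_set_version = screening$sets$version,
    criteria_version = screening$version,
    format = format,
    out_dir = out_dir,
    started = fmt_dttm(as.POSIXct(started, tz = "UTC")),
    finished = fmt_dttm(as.POSIXct(Sys.time(), tz = "UTC")),
    row_counts = list(
      patients = nrow(data$patients),
      cases = nrow(data$cases),
      rule_eligible = sum(decisions$eligible),
      alerts = nrow(al$alerts),
      alerted_cases = length(unique(al$alerts$case_id)),
      classified = nrow(outcomes),
      enrolled = sum(outcomes$status == "enrolled")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(
    cohort = cohort, data = data, decisions = decisions, alerts = al,
    outcomes = outcomes, report = report, manifest = manifest
  ))
}
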
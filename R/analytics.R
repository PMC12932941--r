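# Cohort analytics: allocation accuracy and adherence with confidence
# intervals, team-stratified and provider-level summaries, adherent vs
# non-adherent bias comparisons, and the multivariable logistic adherence
# model. Every proportion is reported with its denominator.

#' Proportion with a 95% confidence interval
#'
#' Wilson score interval by default (better small-sample behavior and never
#' outside `[0, 1]`); the normal (Wald) approximation is available for
#' comparison with intervals computed that way elsewhere. The proportion
#' itself is the exact ratio.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param method `"wilson"` or `"normal"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `proportion_estimate` with fields `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`, `ci_method`.
#' @examples
#' proportion_ci(5424, 10592)
#' @export
proportion_ci <- function(numerator, denominator, method = c("wilson", "normal"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (length(numerator) != 1L || length(denominator) != 1L ||
    is.na(numerator) || is.na(denominator) || denominator <= 0 ||
    numerator < 0 || numerator > denominator) {
    stop("need 0 <= numerator <= denominator and denominator > 0",
      call. = FALSE
    )
  }
  p <- numerator / denominator
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- denominator
  if (method == "wilson") {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  }
  structure(
    list(
      numerator = numerator, denominator = denominator, proportion = p,
      ci_low = max(0, lo), ci_high = min(1, hi), ci_method = method
    ),
    class = "proportion_estimate"
  )
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf(
    "%d/%d = %.1f%% (95%% CI %.1f%%-%.1f%%, %s)\n",
    x$numerator, x$denominator, 100 * x$proportion,
    100 * x$ci_low, 100 * x$ci_high, x$ci_method
  ))
  invisible(x)
}

# appropriate = alerted, no exclusion in fact, recovered outside the ICU
appropriate_statuses <- function() {
  c("enrolled", "nonadherent_stock_sugammadex", "nonadherent_no_study_drug")
}

#' System-performance and adherence metrics for a classified cohort
#'
#' From the enrollment-outcome table of [classify_cases()], computes the
#' study's funnel metrics, each with its denominator and 95% CI:
#' \describe{
#'   \item{allocation_accuracy_pacu}{appropriately allocated alerts /
#'     alerts to non-ICU cases (ICU dispositions analyzed separately because
#'     postoperative disposition cannot be predicted preoperatively).}
#'   \item{allocation_accuracy_all}{appropriately allocated alerts / all
#'     alerted cases.}
#'   \item{misallocation_rate}{alerts that in fact met an exclusion / all
#'     alerted cases.}
#'   \item{icu_share}{ICU dispositions / all alerted cases.}
#'   \item{adherence_overall}{enrolled / appropriately allocated cases
#'     (the accuracy-then-adherence funnel denominator); an
#'     `adherence_all_alerted` variant over every alerted case is also
#'     reported since printed headline rates have used the wider
#'     denominator.}
#'   \item{adherence_by_team}{adherence stratified by care-team category.}
#'   \item{rocuronium_share_pacu}{appropriately allocated cases that
#'     received rocuronium.}
#' }
#'
#' @param outcomes Tibble from [classify_cases()].
#' @param ci_method Passed to [proportion_ci()].
#' @return A list of class `cohort_metrics` (all `proportion_estimate`s,
#'   plus `n_alerted`), or an empty-metrics sentinel when no case was
#'   alerted.
#' @export
cohort_metrics <- function(outcomes, ci_method = "wilson") {
  n_alert <- nrow(outcomes)
  if (!n_alert) {
    return(structure(list(empty = TRUE, n_alerted = 0L),
      class = "cohort_metrics"
    ))
  }
  st <- outcomes$status
  appropriate <- st %in% appropriate_statuses()
  n_app <- sum(appropriate)
  n_icu <- sum(st == "icu_disposition")
  n_mis <- sum(st == "misallocated_exclusion")
  n_enr <- sum(st == "enrolled")

  pc <- function(num, den) {
    if (den > 0) proportion_ci(num, den, method = ci_method) else NULL
  }
  by_team <- lapply(team_levels(), function(tm) {
    sel <- appropriate & outcomes$team == tm
    pc(sum(outcomes$status[sel] == "enrolled"), sum(sel))
  })
  names(by_team) <- team_levels()

  structure(
    list(
      empty = FALSE,
      n_alerted = n_alert,
      allocation_accuracy_pacu = pc(n_app, n_alert - n_icu),
      allocation_accuracy_all = pc(n_app, n_alert),
      misallocation_rate = pc(n_mis, n_alert),
      icu_share = pc(n_icu, n_alert),
      adherence_overall = pc(n_enr, n_app),
      adherence_all_alerted = pc(n_enr, n_alert),
      adherence_by_team = by_team,
      rocuronium_share_pacu = pc(
        sum(appropriate & outcomes$rocuronium_given), n_app
      )
    ),
    class = "cohort_metrics"
  )
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat("<cohort_metrics>\n")
  if (isTRUE(x$empty)) {
    cat("  no alerted cases\n")
    return(invisible(x))
  }
  cat(sprintf("  alerted cases: %d\n", x$n_alerted))
  show <- function(lbl, est) {
    if (!is.null(est)) {
      cat(sprintf(
        "  %-26s %5d/%5d = %5.1f%% (%.1f%%-%.1f%%)\n", lbl,
        est$numerator, est$denominator, 100 * est$proportion,
        100 * est$ci_low, 100 * est$ci_high
      ))
    }
  }
  show("accuracy (PACU)", x$allocation_accuracy_pacu)
  show("accuracy (all alerts)", x$allocation_accuracy_all)
  show("misallocation", x$misallocation_rate)
  show("ICU share", x$icu_share)
  show("adherence (appropriate)", x$adherence_overall)
  show("adherence (all alerted)", x$adherence_all_alerted)
  show("rocuronium share", x$rocuronium_share_pacu)
  for (tm in names(x$adherence_by_team)) {
    show(paste0("  ", tm), x$adherence_by_team[[tm]])
  }
  invisible(x)
}

#' Per-attending adherence and team-stratified box-plot statistics
#'
#' Computes each attending's adherence over their alerted, appropriately
#' allocated cases, and per-team five-number summaries of the attending-level
#' adherence values: median and quartiles by linear interpolation (type 7),
#' whiskers at 1.5 x IQR clamped to observed values. Attendings with fewer
#' cases than `min_cases` are flagged (`low_volume`) but retained.
#'
#' @param outcomes Tibble from [classify_cases()].
#' @param min_cases Minimum alerted-case count before an attending's rate is
#'   considered stable (default 5).
#' @return List with `providers` (tibble: `attending_id`, `cases`,
#'   `enrolled`, `adherence`, `dominant_team`, `low_volume`) and
#'   `team_summaries` (tibble: `team`, `n_providers`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`).
#' @export
provider_distribution <- function(outcomes, min_cases = 5) {
  app <- outcomes[outcomes$status %in% appropriate_statuses(), ]
  providers <- app |>
    dplyr::group_by(.data$attending_id) |>
    dplyr::summarise(
      cases = dplyr::n(),
      enrolled = sum(.data$status == "enrolled"),
      adherence = .data$enrolled / .data$cases,
      dominant_team = names(sort(table(.data$team), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(low_volume = .data$cases < min_cases)

  team_summaries <- providers |>
    dplyr::group_by(team = .data$dominant_team) |>
    dplyr::summarise(
      n_providers = dplyr::n(),
      median = stats::quantile(.data$adherence, 0.5, type = 7, names = FALSE),
      q1 = stats::quantile(.data$adherence, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$adherence, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      whisker_low = .data$q1 - 1.5 * .data$iqr,
      whisker_high = .data$q3 + 1.5 * .data$iqr
    )
  # clamp whiskers to the most extreme observation inside the fence
  for (k in seq_len(nrow(team_summaries))) {
    vals <- providers$adherence[
      providers$dominant_team == team_summaries$team[k]
    ]
    inside <- vals[vals >= team_summaries$whisker_low[k]]
    team_summaries$whisker_low[k] <-
      if (length(inside)) min(inside) else team_summaries$q1[k]
    inside <- vals[vals <= team_summaries$whisker_high[k]]
    team_summaries$whisker_high[k] <-
      if (length(inside)) max(inside) else team_summaries$q3[k]
  }
  list(providers = providers, team_summaries = team_summaries)
}

#' Box plot of provider adherence by team composition
#'
#' @param dist Result of [provider_distribution()].
#' @return A ggplot object.
#' @export
plot_provider_adherence <- function(dist) {
  df <- dist$providers
  df$dominant_team <- factor(df$dominant_team, levels = team_levels())
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$dominant_team, y = .data$adherence)
  ) +
    ggplot2::geom_boxplot(coef = 1.5, fill = "grey85") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "care team composition",
      y = "attending-level adherence",
      title = "Provider adherence to BPA prompts by team composition"
    ) +
    ggplot2::theme_minimal()
}

#' Compare adherent and non-adherent groups on declared variables
#'
#' For each variable, summarises both groups and computes a two-sided
#' p-value from the declared test family: Welch t-test for
#' `continuous_normal` (summary mean +/- SD), Mann-Whitney U for
#' `continuous_skewed` (median \[IQR\]), and chi-square for `categorical`
#' unless any expected cell count is below 5, in which case Fisher's exact
#' test is used. Continuous tests are skipped (with a flag) when either
#' group has fewer than 2 observations. No multiple-testing adjustment is
#' applied; the table mirrors a descriptive bias assessment.
#'
#' @param data Data frame with one row per case.
#' @param group Name of a logical/two-level column splitting the groups
#'   (e.g. adherent vs non-adherent).
#' @param vars Named character vector mapping variable name to role:
#'   `"continuous_normal"`, `"continuous_skewed"`, or `"categorical"`.
#' @return Tibble: `variable`, `role`, `summary_group1`, `summary_group2`,
#'   `test`, `p_value`, `skipped`.
#' @export
compare_groups <- function(data, group, vars) {
  g <- data[[group]]
  if (is.logical(g)) g <- factor(g, levels = c(TRUE, FALSE))
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  lev <- levels(g)

  one <- function(var, role) {
    x <- data[[var]]
    x1 <- x[g == lev[1] & !is.na(x)]
    x2 <- x[g == lev[2] & !is.na(x)]
    skipped <- FALSE
    p <- NA_real_
    test <- NA_character_
    if (role == "continuous_normal") {
      s1 <- sprintf("%.1f ± %.1f", mean(x1), stats::sd(x1))
      s2 <- sprintf("%.1f ± %.1f", mean(x2), stats::sd(x2))
      test <- "t"
      if (length(x1) < 2 || length(x2) < 2) {
        skipped <- TRUE
      } else {
        p <- stats::t.test(x1, x2)$p.value
      }
    } else if (role == "continuous_skewed") {
      q <- function(v) {
        qq <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
        sprintf("%.1f [%.1f-%.1f]", qq[2], qq[1], qq[3])
      }
      s1 <- q(x1)
      s2 <- q(x2)
      test <- "mann_whitney"
      if (length(x1) < 2 || length(x2) < 2) {
        skipped <- TRUE
      } else {
        p <- stats::wilcox.test(x1, x2, exact = FALSE)$p.value
      }
    } else if (role == "categorical") {
      tab <- table(factor(x[!is.na(x)]), g[!is.na(x)])
      pct <- function(col) {
        paste(sprintf(
          "%s: %d (%.1f%%)", rownames(tab), tab[, col],
          100 * tab[, col] / max(1, sum(tab[, col]))
        ), collapse = ", ")
      }
      s1 <- pct(1)
      s2 <- pct(2)
      if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
        skipped <- TRUE
        test <- "chi_square"
      } else {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          test <- "fisher"
          p <- stats::fisher.test(tab)$p.value
        } else {
          test <- "chi_square"
          p <- stats::chisq.test(tab, correct = FALSE)$p.value
        }
      }
    } else {
      stop("unknown variable role: '", role, "'", call. = FALSE)
    }
    tibble::tibble(
      variable = var, role = role,
      summary_group1 = s1, summary_group2 = s2,
      test = test, p_value = p, skipped = skipped
    )
  }
  dplyr::bind_rows(purrr::map2(names(vars), unname(vars), one))
}

#' Multivariable logistic model of provider adherence
#'
#' Fits `enrolled ~ covariates` by maximum-likelihood logistic regression on
#' the subset the adherence question is well-posed for: alerted,
#' appropriately allocated cases that recovered in the PACU and received
#' rocuronium (so reversal was actually at issue). Reports odds ratios with
#' Wald 95% CIs and p-values. Reference levels are the first factor level of
#' each covariate (team reference: `full_team`). Complete separation and
#' non-convergence are detected and reported as structured warnings naming
#' the offending covariate.
#'
#' @param model_frame Data frame with one row per case containing the logical
#'   outcome column `enrolled` plus the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A list of class `adherence_model` with `terms` (tibble:
#'   `term`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`), `n_fit`,
#'   `subset_rule`, `converged`, `separation_terms`, and the underlying
#'   `fit`.
#' @export
fit_adherence_model <- function(model_frame,
                                covariates = setdiff(
                                  names(model_frame), "enrolled"
                                )) {
  stopifnot("enrolled" %in% names(model_frame))
  keep <- stats::complete.cases(model_frame[c("enrolled", covariates)])
  df <- model_frame[keep, , drop = FALSE]
  # drop covariates with a single observed level
  usable <- covariates[vapply(covariates, function(v) {
    x <- df[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, usable)
  if (length(dropped)) {
    warning(
      "covariate(s) with a single level dropped: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  if (!length(usable)) stop("no usable covariates", call. = FALSE)
  fml <- stats::reformulate(usable, response = "enrolled")
  fit <- suppressWarnings(
    stats::glm(fml, data = df, family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  z <- stats::qnorm(0.975)
  terms <- tibble::tibble(
    term = rownames(co),
    odds_ratio = unname(exp(est)),
    ci_low = unname(exp(est - z * se)),
    ci_high = unname(exp(est + z * se)),
    p_value = unname(co[, "Pr(>|z|)"])
  )
  terms <- terms[terms$term != "(Intercept)", ]
  sep <- terms$term[abs(log(terms$odds_ratio)) > 10 | terms$ci_high > 1e6]
  if (!fit$converged) {
    warning("adherence model did not converge", call. = FALSE)
  }
  if (length(sep)) {
    warning(
      "possible complete separation in term(s): ",
      paste(sep, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      terms = terms,
      n_fit = nrow(df),
      subset_rule = "alerted, appropriately allocated, PACU recovery, rocuronium given",
      converged = fit$converged,
      separation_terms = sep,
      fit = fit
    ),
    class = "adherence_model"
  )
}

#' @export
print.adherence_model <- function(x, ...) {
  cat(sprintf(
    "<adherence_model> n = %d (%s)\n", x$n_fit, x$subset_rule
  ))
  t <- x$terms
  for (k in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-32s OR %5.2f (%.2f-%.2f)  p=%.3g\n",
      t$term[k], t$odds_ratio[k], t$ci_low[k], t$ci_high[k], t$p_value[k]
    ))
  }
  invisible(x)
}

#' Build the adherence-model frame from pipeline outputs
#'
#' Joins outcomes, cases, patients and the eligibility table into the
#' analysis frame for [fit_adherence_model()], restricted to appropriately
#' allocated PACU cases that received rocuronium. Covariates: team category
#' (reference `full_team`), the three delay flags, long surgery (> 2
#' scheduled hours), age in decades, BMI category, the low-hemoglobin and
#' low-SpO2 criterion flags, and ASA class when present.
#'
#' @param data An `ehr_dataset`.
#' @param outcomes Tibble from [classify_cases()].
#' @param decisions Eligibility table from [screen_cases()].
#' @return Tibble ready for [fit_adherence_model()].
#' @export
adherence_model_frame <- function(data, outcomes, decisions) {
  sub <- outcomes[
    outcomes$status %in% appropriate_statuses() &
      outcomes$disposition == "pacu" & outcomes$rocuronium_given,
  ]
  ci <- match(sub$case_id, data$cases$case_id)
  cases <- data$cases[ci, ]
  p <- data$patients[match(cases$patient_id, data$patients$patient_id), ]
  di <- match(sub$case_id, decisions$case_id)
  age <- age_years(p$birth_date, as.Date(cases$scheduled_start, tz = "UTC"))
  tibble::tibble(
    case_id = sub$case_id,
    enrolled = sub$status == "enrolled",
    team = factor(sub$team, levels = team_levels()),
    delay_patient = cases$delay_patient,
    delay_scheduling = cases$delay_scheduling,
    delay_staff = cases$delay_staff,
    long_surgery = decisions$long_surgery[di],
    age_decades = age / 10,
    bmi_gt_40 = decisions$bmi_gt_40[di],
    low_hemoglobin = decisions$low_hemoglobin[di],
    low_preop_spo2 = decisions$low_preop_spo2[di],
    service = factor(cases$service)
  )
}
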
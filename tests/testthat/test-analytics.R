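test_that("proportions and Wilson/Wald intervals behave", {
  est <- proportion_ci(5424, 10592)
  expect_equal(round(100 * est$proportion, 1), 51.2)
  expect_true(est$ci_low <= est$proportion && est$proportion <= est$ci_high)

  z <- proportion_ci(0, 50)
  expect_equal(z$proportion, 0)
  expect_equal(z$ci_low, 0)

  # closed-form Wilson oracle, written out from the textbook formula
  n <- 100
  x <- 57
  p <- x / n
  zq <- qnorm(0.975)
  denom <- 1 + zq^2 / n
  mid <- (p + zq^2 / (2 * n)) / denom
  se <- zq * sqrt((p * (1 - p) + zq^2 / (4 * n)) / n) / denom
  w <- proportion_ci(x, n, method = "wilson")
  expect_equal(w$ci_low, mid - se, tolerance = 1e-9)
  expect_equal(w$ci_high, mid + se, tolerance = 1e-9)

  wald <- proportion_ci(57, 100, method = "normal")
  expect_equal(wald$ci_low, p - zq * sqrt(p * (1 - p) / n), tolerance = 1e-12)

  expect_error(proportion_ci(5, 0), "denominator")
  expect_error(proportion_ci(7, 5), "denominator")
  expect_error(proportion_ci(-1, 5), "denominator")
})

ten_case_outcomes <- function() {
  tibble::tibble(
    case_id = sprintf("C%02d", 1:10),
    status = c(
      rep("misallocated_exclusion", 2), "icu_disposition",
      rep("enrolled", 4), rep("nonadherent_stock_sugammadex", 2),
      "nonadherent_no_study_drug"
    ),
    rocuronium_given = c(rep(TRUE, 8), FALSE, FALSE),
    disposition = c(rep("pacu", 2), "icu_unplanned_transfer", rep("pacu", 7)),
    attending_id = rep(c("A1", "A2"), 5),
    team = rep(c("full_team", "solo_attending"), 5)
  )
}

test_that("cohort metrics reproduce a hand-counted fixture", {
  m <- cohort_metrics(ten_case_outcomes())
  expect_equal(m$misallocation_rate$proportion, 2 / 10)
  expect_equal(m$icu_share$proportion, 1 / 10)
  expect_equal(m$adherence_overall$proportion, 4 / 7)
  expect_equal(m$adherence_overall$denominator, 7)
  expect_equal(m$allocation_accuracy_all$proportion, 7 / 10)
  expect_equal(m$allocation_accuracy_pacu$proportion, 7 / 9)
  expect_gte(
    m$allocation_accuracy_pacu$proportion,
    m$allocation_accuracy_all$proportion
  )
  expect_equal(m$rocuronium_share_pacu$numerator, 5)
  expect_output(print(m), "adherence")
})

test_that("metrics are invariant to row order and empty cohorts are sentinels", {
  oc <- ten_case_outcomes()
  set.seed(1)
  m1 <- cohort_metrics(oc)
  m2 <- cohort_metrics(oc[sample(nrow(oc)), ])
  expect_equal(m1, m2)
  empty <- cohort_metrics(oc[0, ])
  expect_true(empty$empty)
  expect_equal(empty$n_alerted, 0L)
})

test_that("all reported proportions and intervals live in [0, 1]", {
  co <- generate_cohort(sim_config(n_patients = 500, seed = 77))
  dec <- screen_cases(co$data)
  al <- run_alerts(co$data, dec)
  m <- cohort_metrics(classify_cases(co$data, al$alerts))
  ests <- c(
    list(
      m$allocation_accuracy_pacu, m$allocation_accuracy_all,
      m$misallocation_rate, m$icu_share, m$adherence_overall,
      m$adherence_all_alerted, m$rocuronium_share_pacu
    ),
    m$adherence_by_team
  )
  for (e in ests) {
    if (is.null(e)) next
    expect_true(e$numerator <= e$denominator)
    expect_true(e$ci_low >= 0 && e$ci_low <= e$proportion)
    expect_true(e$ci_high <= 1 && e$ci_high >= e$proportion)
  }
})

test_that("provider adherence and quartiles match a sort-based oracle", {
  oc <- ten_case_outcomes()
  dist <- provider_distribution(oc, min_cases = 3)
  a1 <- dist$providers[dist$providers$attending_id == "A1", ]
  expect_equal(a1$cases, 3L) # A1's misallocated and ICU cases drop out
  expect_equal(a1$enrolled, 2L)
  expect_equal(a1$adherence, 2 / 3)
  expect_equal(a1$dominant_team, "full_team")

  # quartile convention against a naive sorted-vector reference
  set.seed(42)
  vals <- runif(31)
  q <- quantile(vals, c(.25, .5, .75), type = 7, names = FALSE)
  s <- sort(vals)
  ref <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(q, c(ref(.25), ref(.5), ref(.75)), tolerance = 1e-12)

  one <- tibble::tibble(
    case_id = sprintf("C%d", 1:4),
    status = c("enrolled", "enrolled", "nonadherent_no_study_drug", "nonadherent_stock_sugammadex"),
    rocuronium_given = TRUE,
    disposition = "pacu",
    attending_id = "A9",
    team = "full_team"
  )
  d1 <- provider_distribution(one)
  expect_equal(d1$providers$adherence, 0.5)
  expect_true(d1$providers$low_volume)
})

test_that("a bimodal solo mixture widens the solo IQR beyond the full-team IQR", {
  cfg <- sim_config(
    n_patients = 6000, seed = 61,
    team_mix = c(
      full_team = 0.5, attending_crna = 0, attending_resident = 0,
      solo_attending = 0.5
    ),
    provider_team_consistency = 1
  )
  co <- generate_cohort(cfg)
  dec <- screen_cases(co$data)
  al <- run_alerts(co$data, dec)
  oc <- classify_cases(co$data, al$alerts)
  dist <- provider_distribution(oc)
  tsumm <- dist$team_summaries
  iqr <- function(team) {
    r <- tsumm[tsumm$team == team, ]
    r$q3 - r$q1
  }
  expect_gt(iqr("solo_attending"), iqr("full_team"))
})

test_that("group comparisons pick the declared tests and honor the Fisher rule", {
  df <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), each = 20),
    x_norm = rep(c(1.0, 2.0, 3.0, 4.0), 10),
    x_skew = rep(c(1, 5, 2, 9), 10),
    flag = rep(c(TRUE, FALSE), 20)
  )
  res <- compare_groups(df, "grp", c(
    x_norm = "continuous_normal", x_skew = "continuous_skewed",
    flag = "categorical"
  ))
  # identical groups: exact tests give p = 1
  expect_equal(res$p_value[res$variable == "x_norm"], 1, tolerance = 1e-9)
  expect_equal(res$p_value[res$variable == "flag"], 1, tolerance = 1e-9)
  expect_equal(res$test, c("t", "mann_whitney", "chi_square"))

  # balanced 2x2 (10,10 / 10,10): chi-square, no association
  expect_equal(res$p_value[res$variable == "flag"], 1)

  # small cells flip to Fisher
  df2 <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), each = 6),
    rare = c(rep(TRUE, 2), rep(FALSE, 4), rep(TRUE, 1), rep(FALSE, 5))
  )
  res2 <- compare_groups(df2, "grp", c(rare = "categorical"))
  expect_equal(res2$test, "fisher")

  # continuous tests are skipped, not crashed, on tiny groups
  df3 <- tibble::tibble(grp = c(TRUE, FALSE, FALSE), v = c(1, 2, 3))
  res3 <- compare_groups(df3, "grp", c(v = "continuous_normal"))
  expect_true(res3$skipped)
  expect_error(compare_groups(df3, "v", c(grp = "categorical")), "two levels")
})

test_that("p-values are uniform under the null (KS sanity)", {
  set.seed(202)
  ps <- replicate(300, {
    a <- rnorm(25)
    b <- rnorm(25)
    stats::t.test(a, b)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("logistic model matches the closed-form odds ratio on a 2x2 design", {
  # balanced saturated design: OR = (a*d)/(b*c)
  df <- tibble::tibble(
    enrolled = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 15, 25)),
    exposed = rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 15, 25))
  )
  fit <- fit_adherence_model(df, covariates = "exposed")
  expect_equal(fit$terms$odds_ratio, (30 * 25) / (10 * 15), tolerance = 1e-6)
  expect_equal(fit$n_fit, 80)
})

test_that("complete separation is detected and reported", {
  df <- tibble::tibble(
    enrolled = rep(c(TRUE, FALSE), each = 20),
    sep = rep(c(TRUE, FALSE), each = 20),
    other = rnorm(40)
  )
  expect_warning(
    fit_adherence_model(df, covariates = c("sep", "other")),
    "separation"
  )
})

test_that("single-level covariates are dropped with a warning", {
  df <- tibble::tibble(
    enrolled = rep(c(TRUE, FALSE), 20),
    const = TRUE,
    x = rnorm(40)
  )
  expect_warning(
    fit <- fit_adherence_model(df, covariates = c("const", "x")),
    "single level"
  )
  expect_false("constTRUE" %in% fit$terms$term)
})
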
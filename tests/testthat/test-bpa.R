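eligible_toy <- function(...) {
  toy_dataset(
    patients = base_patient(preop_sleep_apnea = TRUE),
    cases = base_case(...)
  )
}

test_that("should_fire gates on eligibility, exclusions, site, hours, window", {
  cfg <- availability_config()
  data <- eligible_toy()
  dec <- screen_cases(data)
  case <- data$cases[1, ]
  at <- function(x) ts(x)

  a <- should_fire(case, dec[1, ], cfg, now = at("2023-05-09 10:00:00"))
  expect_equal(nrow(a), 1L)
  expect_equal(a$context, "preop")
  a <- should_fire(case, dec[1, ], cfg, now = at("2023-05-10 09:30:00"))
  expect_equal(a$context, "intraop")

  # ineligible patient
  d0 <- toy_dataset()
  r <- should_fire(d0$cases[1, ], screen_cases(d0)[1, ], cfg,
    now = at("2023-05-09 10:00:00")
  )
  expect_equal(nrow(r), 0L)
  expect_equal(attr(r, "reason"), "ineligible")

  # excluded patient
  dx <- toy_dataset(
    patients = base_patient(preop_sleep_apnea = TRUE, gfr_latest = 20)
  )
  r <- should_fire(dx$cases[1, ], screen_cases(dx)[1, ], cfg,
    now = at("2023-05-09 10:00:00")
  )
  expect_equal(attr(r, "reason"), "excluded")

  # uncovered site
  ds <- eligible_toy(site = "ambulatory_center")
  r <- should_fire(ds$cases[1, ], screen_cases(ds)[1, ], cfg,
    now = at("2023-05-09 10:00:00")
  )
  expect_equal(attr(r, "reason"), "site")

  # pharmacy closed
  r <- should_fire(case, dec[1, ], cfg, now = at("2023-05-09 23:30:00"))
  expect_equal(attr(r, "reason"), "hours")
  r <- should_fire(case, dec[1, ], cfg, now = at("2023-05-09 06:59:00"))
  expect_equal(attr(r, "reason"), "hours")

  # outside the lead window / after the case
  r <- should_fire(case, dec[1, ], cfg, now = at("2023-05-01 10:00:00"))
  expect_equal(attr(r, "reason"), "window")
  r <- should_fire(case, dec[1, ], cfg, now = at("2023-05-10 12:00:00"))
  expect_equal(attr(r, "reason"), "window") # 90-min case is over

  # idempotence against the ledger
  ledger <- should_fire(case, dec[1, ], cfg, now = at("2023-05-09 10:00:00"))
  r <- should_fire(case, dec[1, ], cfg,
    now = at("2023-05-09 11:00:00"),
    ledger = ledger
  )
  expect_equal(attr(r, "reason"), "duplicate")

  other <- toy_dataset(cases = base_case(case_id = "C9"))
  expect_error(
    should_fire(case, screen_cases(other)[1, ], cfg,
      now = at("2023-05-09 10:00:00")
    ),
    "does not belong"
  )
})

test_that("run_alerts records at most one alert per case/context and replays identically", {
  data <- eligible_toy()
  dec <- screen_cases(data)
  cfg <- availability_config()
  polls <- tibble::tibble(
    case_id = "C1",
    poll_time = ts(c(
      "2023-05-09 09:00:00", "2023-05-09 15:00:00", # two preop polls
      "2023-05-10 09:10:00", "2023-05-10 09:40:00" # two intraop polls
    ))
  )
  a1 <- run_alerts(data, dec, cfg, polls = polls)
  expect_equal(nrow(a1$alerts), 2L)
  expect_setequal(a1$alerts$context, c("preop", "intraop"))
  expect_equal(sum(a1$log$reason == "duplicate", na.rm = TRUE), 2L)
  a2 <- run_alerts(data, dec, cfg, polls = polls)
  expect_identical(a1$alerts, a2$alerts)
  expect_error(
    run_alerts(data, dec, cfg, polls = tibble::tibble(
      case_id = "NOPE", poll_time = ts("2023-05-09 09:00:00")
    )),
    "unknown case_id"
  )
})

test_that("team classification partitions all rosters", {
  grid <- expand.grid(crna = c(TRUE, FALSE), res = c(TRUE, FALSE))
  got <- classify_team(grid$crna, grid$res)
  expect_setequal(got, c(
    "full_team", "attending_crna", "attending_resident", "solo_attending"
  ))
  expect_equal(classify_team(TRUE, TRUE), "full_team")
  expect_equal(classify_team(FALSE, FALSE), "solo_attending")
  expect_equal(classify_team(TRUE, FALSE), "attending_crna")
  expect_equal(classify_team(FALSE, TRUE), "attending_resident")
})

test_that("enrollment classification follows the five-way precedence", {
  alert <- tibble::tibble(
    case_id = "C1", fired_at = ts("2023-05-09 10:00:00"),
    context = "preop", majors_met = 1L, minors_met = 0L
  )
  status_of <- function(data) classify_cases(data, alert)$status[1]

  # study-pathway sugammadex => enrolled
  d <- eligible_toy()
  d$meds <- med_row("C1", "sugammadex", "study_pathway", via_bpa = TRUE)
  expect_equal(status_of(d), "enrolled")

  # stock sugammadex only => non-adherent (stock bypass)
  d$meds <- med_row("C1", "sugammadex", "standard_stock")
  expect_equal(status_of(d), "nonadherent_stock_sugammadex")

  # no reversal through any pathway
  d$meds <- med_row("C1", "rocuronium")
  oc <- classify_cases(d, alert)
  expect_equal(oc$status[1], "nonadherent_no_study_drug")
  expect_true(oc$rocuronium_given[1])

  # ICU disposition outranks meds
  d2 <- toy_dataset(
    patients = base_patient(preop_sleep_apnea = TRUE),
    cases = base_case(disposition = "icu_unplanned_transfer"),
    meds = med_row("C1", "sugammadex", "study_pathway", via_bpa = TRUE)
  )
  expect_equal(status_of(d2), "icu_disposition")

  # a post-hoc-visible exclusion outranks everything
  d3 <- toy_dataset(
    patients = base_patient(
      preop_sleep_apnea = TRUE, neuromuscular_disease = TRUE,
      exclusion_documented_at = ts("2023-05-12 08:00:00")
    ),
    cases = base_case(disposition = "icu_unplanned_transfer"),
    meds = med_row("C1", "sugammadex", "study_pathway", via_bpa = TRUE)
  )
  expect_equal(status_of(d3), "misallocated_exclusion")

  # unalerted cases are outside the classifier's domain
  expect_error(
    classify_enrollment(eligible_toy(), "C1", alert[0, ]),
    "never alerted"
  )
})

test_that("every alerted case gets exactly one status", {
  co <- generate_cohort(sim_config(n_patients = 600, seed = 3))
  dec <- screen_cases(co$data)
  al <- run_alerts(co$data, dec)
  oc <- classify_cases(co$data, al$alerts)
  expect_setequal(oc$case_id, unique(al$alerts$case_id))
  expect_equal(anyDuplicated(oc$case_id), 0L)
  expect_true(all(oc$status %in% c(
    "misallocated_exclusion", "icu_disposition", "enrolled",
    "nonadherent_stock_sugammadex", "nonadherent_no_study_drug"
  )))
})

test_that("the funnel is contained: enrolled within alerted within eligible", {
  co <- generate_cohort(sim_config(n_patients = 800, seed = 29))
  dec <- screen_cases(co$data)
  al <- run_alerts(co$data, dec)
  oc <- classify_cases(co$data, al$alerts)
  eligible <- dec$case_id[dec$eligible]
  alerted <- unique(al$alerts$case_id)
  enrolled <- oc$case_id[oc$status == "enrolled"]
  expect_true(all(alerted %in% eligible))
  expect_true(all(enrolled %in% alerted))
  expect_true(length(enrolled) <= length(alerted))
  expect_true(length(alerted) <= length(eligible))
})
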
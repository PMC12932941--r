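# Alert state machine: an eligible case fires a best-practice advisory (BPA)
# at a polling instant when the site is covered, the OR pharmacy is open and
# the instant falls in the preop lead window or inside the case itself. At
# most one alert is recorded per case per context; replaying the same polls
# yields the same ledger.

#' Alert availability configuration
#'
#' Where and when BPA alerts may fire: the covered sites, the OR pharmacy's
#' daily open/close local times (alerts are suppressed outside them so study
#' medication can be tracked), the preoperative lead window during which a
#' preop alert may show, and the fixed offsets used to derive default polling
#' instants from a case's schedule.
#'
#' @param eligible_sites Character vector of covered site identifiers.
#' @param pharmacy_open,pharmacy_close Daily local times, `"HH:MM"`;
#'   open must precede close.
#' @param preop_lead_days Days before the scheduled start during which a
#'   preop alert may fire.
#' @param preop_poll_offset_hours Hours before the scheduled start of the
#'   default preop polling instant.
#' @param intraop_poll_offset_min Minutes after the scheduled start of the
#'   default intraop polling instant.
#' @return A list of class `availability_config`.
#' @export
availability_config <- function(eligible_sites = c("main_campus", "west_campus"),
                                pharmacy_open = "07:00",
                                pharmacy_close = "22:00",
                                preop_lead_days = 7,
                                preop_poll_offset_hours = 24,
                                intraop_poll_offset_min = 5) {
  stopifnot(length(eligible_sites) >= 1)
  open_s <- hm_to_sec(pharmacy_open)
  close_s <- hm_to_sec(pharmacy_close)
  if (!(open_s < close_s)) {
    stop("pharmacy_open must precede pharmacy_close", call. = FALSE)
  }
  structure(
    list(
      eligible_sites = eligible_sites,
      pharmacy_open = pharmacy_open, pharmacy_close = pharmacy_close,
      open_sec = open_s, close_sec = close_s,
      preop_lead_days = preop_lead_days,
      preop_poll_offset_hours = preop_poll_offset_hours,
      intraop_poll_offset_min = intraop_poll_offset_min
    ),
    class = "availability_config"
  )
}

hm_to_sec <- function(hm) {
  parts <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1]])
  stopifnot(length(parts) == 2, !anyNA(parts))
  parts[1] * 3600 + parts[2] * 60
}

sec_of_day <- function(t) {
  as.integer(format(t, "%H", tz = "UTC")) * 3600 +
    as.integer(format(t, "%M", tz = "UTC")) * 60 +
    as.integer(format(t, "%S", tz = "UTC"))
}

#' Default polling instants for a set of cases
#'
#' The system is modeled at discrete polling instants rather than a
#' continuous clock so replays are deterministic: one preop poll at a fixed
#' offset before the scheduled start and one intraop poll shortly after it.
#'
#' @param cases The `cases` table.
#' @param config An [availability_config()].
#' @return Tibble with `case_id` and `poll_time`, in time order.
#' @export
default_polls <- function(cases, config = availability_config()) {
  polls <- tibble::tibble(
    case_id = rep(cases$case_id, 2L),
    poll_time = c(
      cases$scheduled_start - config$preop_poll_offset_hours * 3600,
      cases$scheduled_start + config$intraop_poll_offset_min * 60
    )
  )
  polls[order(polls$poll_time, polls$case_id), ]
}

#' Decide whether a BPA alert fires at one polling instant
#'
#' An alert fires iff the eligibility decision is included with no exclusion
#' flag set, the case's site is covered, the instant falls within pharmacy
#' hours, and the instant lies in the preop lead window (context `preop`) or
#' inside the scheduled case (context `intraop`). The call is idempotent
#' against the supplied ledger: a case/context pair already alerted never
#' fires again.
#'
#' @param case One-row slice of the `cases` table.
#' @param decision The case's row of an eligibility table from
#'   [screen_cases()].
#' @param config An [availability_config()].
#' @param now A POSIXct polling instant.
#' @param ledger Existing alert ledger (tibble with `case_id`, `context`),
#'   or `NULL`.
#' @return A one-row alert tibble (`case_id`, `fired_at`, `context`,
#'   `majors_met`, `minors_met`); when no alert fires, a zero-row tibble
#'   whose `reason` attribute is one of the stable codes `ineligible`,
#'   `excluded`, `site`, `hours`, `window`, `duplicate`.
#' @export
should_fire <- function(case, decision, config = availability_config(),
                        now, ledger = NULL) {
  stopifnot(nrow(case) == 1L, nrow(decision) == 1L)
  if (!identical(case$case_id, decision$case_id)) {
    stop("decision does not belong to this case", call. = FALSE)
  }
  refuse <- function(reason) {
    out <- tibble::tibble(
      case_id = character(),
      fired_at = as.POSIXct(character(), tz = "UTC"),
      context = character(),
      majors_met = integer(), minors_met = integer()
    )
    attr(out, "reason") <- reason
    out
  }
  if (!decision$included) {
    return(refuse("ineligible"))
  }
  if (decision$excluded_any) {
    return(refuse("excluded"))
  }
  if (!(case$site %in% config$eligible_sites)) {
    return(refuse("site"))
  }
  s <- sec_of_day(now)
  if (s < config$open_sec || s >= config$close_sec) {
    return(refuse("hours"))
  }
  start <- case$scheduled_start
  end <- start + case$scheduled_duration_min * 60
  context <- if (now >= start - config$preop_lead_days * 86400 && now < start) {
    "preop"
  } else if (now >= start && now < end) {
    "intraop"
  } else {
    return(refuse("window"))
  }
  if (!is.null(ledger) && nrow(ledger) &&
    any(ledger$case_id == case$case_id & ledger$context == context)) {
    return(refuse("duplicate"))
  }
  tibble::tibble(
    case_id = case$case_id, fired_at = now, context = context,
    majors_met = decision$majors_met, minors_met = decision$minors_met
  )
}

#' Run the alert state machine over a poll schedule
#'
#' Applies [should_fire()] semantics to every polling instant (default: the
#' deterministic instants of [default_polls()]) and returns the alert ledger
#' plus a per-poll log with the stable reason code for every instant that did
#' not fire. At most one alert is recorded per case per context.
#'
#' @param data An `ehr_dataset`.
#' @param decisions Eligibility table from [screen_cases()] for the same
#'   cases.
#' @param config An [availability_config()].
#' @param polls Tibble of polling instants (`case_id`, `poll_time`);
#'   default [default_polls()].
#' @return List with `alerts` (ledger tibble) and `log` (one row per poll:
#'   `case_id`, `poll_time`, `fired`, `context`, `reason`).
#' @export
run_alerts <- function(data, decisions, config = availability_config(),
                       polls = NULL) {
  cases <- data$cases
  if (is.null(polls)) polls <- default_polls(cases, config)
  ci <- match(polls$case_id, cases$case_id)
  if (anyNA(ci)) {
    stop(
      "polls reference unknown case_id: ",
      paste(unique(polls$case_id[is.na(ci)]), collapse = ", "),
      call. = FALSE
    )
  }
  di <- match(polls$case_id, decisions$case_id)
  if (anyNA(di)) {
    stop("decisions missing for polled case(s)", call. = FALSE)
  }
  polls <- polls[order(polls$poll_time, polls$case_id), ]
  ci <- match(polls$case_id, cases$case_id)
  di <- match(polls$case_id, decisions$case_id)

  start <- cases$scheduled_start[ci]
  end <- start + cases$scheduled_duration_min[ci] * 60
  now <- polls$poll_time
  s <- sec_of_day(now)

  context <- rep(NA_character_, nrow(polls))
  context[now >= start - config$preop_lead_days * 86400 & now < start] <- "preop"
  context[now >= start & now < end] <- "intraop"

  reason <- rep(NA_character_, nrow(polls))
  reason[is.na(context)] <- "window"
  reason[s < config$open_sec | s >= config$close_sec] <- "hours"
  reason[!(cases$site[ci] %in% config$eligible_sites)] <- "site"
  reason[decisions$excluded_any[di]] <- "excluded"
  reason[!decisions$included[di]] <- "ineligible"

  fired <- is.na(reason)
  # idempotence: keep the first firing per (case, context)
  key <- paste(polls$case_id, context, sep = "\r")
  dup <- fired & duplicated(ifelse(fired, key, NA_character_)) &
    !is.na(context)
  reason[dup] <- "duplicate"
  fired <- is.na(reason)

  alerts <- tibble::tibble(
    case_id = polls$case_id[fired],
    fired_at = now[fired],
    context = context[fired],
    majors_met = decisions$majors_met[di][fired],
    minors_met = decisions$minors_met[di][fired]
  )
  log <- tibble::tibble(
    case_id = polls$case_id,
    poll_time = now,
    fired = fired,
    context = context,
    reason = reason
  )
  list(alerts = alerts, log = log)
}

#' Classify a care team roster
#'
#' The four categories partition every roster: `full_team` (CRNA and
#' resident both present), `attending_crna`, `attending_resident`,
#' `solo_attending`.
#'
#' @param crna_present,resident_present Logical vectors.
#' @return Character vector of team categories.
#' @export
classify_team <- function(crna_present, resident_present) {
  dplyr::case_when(
    crna_present & resident_present ~ "full_team",
    crna_present ~ "attending_crna",
    resident_present ~ "attending_resident",
    .default = "solo_attending"
  )
}

team_levels <- function() {
  c("full_team", "attending_crna", "attending_resident", "solo_attending")
}

enrollment_statuses <- function() {
  c(
    "misallocated_exclusion", "icu_disposition", "enrolled",
    "nonadherent_stock_sugammadex", "nonadherent_no_study_drug"
  )
}

#' Classify the enrollment outcome of every alerted case
#'
#' Maps each alerted case to exactly one of five statuses under a strict
#' precedence: (1) `misallocated_exclusion` when an exclusion criterion was
#' in fact satisfied (judged post hoc, with every documented fact visible);
#' (2) `icu_disposition` when the patient was admitted to the ICU instead of
#' recovering in the PACU — planned or unplanned — regardless of medications;
#' (3) `enrolled` when sugammadex was administered through the BPA-linked
#' study pathway; (4) `nonadherent_stock_sugammadex` when only standard-stock
#' sugammadex was given; (5) `nonadherent_no_study_drug` otherwise.
#' `rocuronium_given` is read from the medication list. Unalerted cases are
#' outside this classifier's domain and are not returned.
#'
#' @param data An `ehr_dataset`.
#' @param alerts Alert ledger from [run_alerts()].
#' @param config A [screening_config()] (used for the post-hoc exclusion
#'   re-evaluation).
#' @return Tibble of class `enrollment_outcomes`: one row per alerted case
#'   with `case_id`, `status`, `rocuronium_given`, `disposition`,
#'   `attending_id`, `team`.
#' @export
classify_cases <- function(data, alerts, config = screening_config()) {
  alerted <- unique(alerts$case_id)
  if (!all(alerted %in% data$cases$case_id)) {
    stop("alert ledger references unknown case_id", call. = FALSE)
  }
  m <- data$meds
  bad <- m$source == "study_pathway" &
    (m$drug != "sugammadex" | !m$ordered_via_bpa)
  if (any(bad)) {
    stop(
      "contradictory medication record(s): study_pathway without ",
      "BPA-ordered sugammadex (case ",
      paste(unique(m$case_id[bad]), collapse = ", "), ")",
      call. = FALSE
    )
  }
  ci <- match(alerted, data$cases$case_id)
  cases <- data$cases[ci, ]
  ex <- screen_exclusions(data, config, as_of = "post_hoc")
  excluded <- ex$excluded_any[match(alerted, ex$case_id)]

  med_of <- function(drug, source = NULL) {
    sel <- m$drug == drug
    if (!is.null(source)) sel <- sel & m$source %in% source
    alerted %in% m$case_id[sel]
  }
  study_sugg <- med_of("sugammadex", "study_pathway")
  stock_sugg <- med_of("sugammadex", "standard_stock")
  rocu <- med_of("rocuronium")
  icu <- cases$disposition %in% c("icu_direct", "icu_unplanned_transfer")

  status <- dplyr::case_when(
    excluded ~ "misallocated_exclusion",
    icu ~ "icu_disposition",
    study_sugg ~ "enrolled",
    stock_sugg ~ "nonadherent_stock_sugammadex",
    .default = "nonadherent_no_study_drug"
  )
  out <- tibble::tibble(
    case_id = alerted,
    status = status,
    rocuronium_given = rocu,
    disposition = cases$disposition,
    attending_id = cases$attending_id,
    team = classify_team(cases$crna_present, cases$resident_present)
  )
  structure(out, class = c("enrollment_outcomes", class(out)))
}

#' Classify one alerted case
#'
#' Single-case convenience wrapper around [classify_cases()].
#'
#' @inheritParams classify_cases
#' @param case_id The alerted case to classify.
#' @return One-row outcome tibble.
#' @export
classify_enrollment <- function(data, case_id, alerts,
                                config = screening_config()) {
  if (!case_id %in% alerts$case_id) {
    stop(
      "case '", case_id, "' was never alerted; unalerted cases are outside ",
      "the enrollment classifier's domain",
      call. = FALSE
    )
  }
  out <- classify_cases(data, alerts[alerts$case_id == case_id, ], config)
  out[out$case_id == case_id, ]
}
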
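#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Column dictionary for the interchange tables. type is one of
# chr / lgl / dbl / int / date / dttm. Timestamps are timezone-naive local
# clinical time at second resolution; they are carried as POSIXct in UTC by
# convention so arithmetic never crosses a DST boundary.
ehr_schema <- function() {
  list(
    patients = c(
      patient_id = "chr", birth_date = "date", sex = "chr",
      pregnant_or_lactating = "lgl", allergies = "chr",
      preop_copd = "lgl", preop_supplemental_o2 = "lgl",
      preop_lung_transplant = "lgl", preop_recent_uri = "lgl",
      preop_sleep_apnea = "lgl",
      neuromuscular_disease = "lgl", gfr_latest = "dbl",
      vent_hours_pre_admission = "dbl", tracheostomy_pre_admission = "lgl",
      prior_max_intubation_attempts = "int",
      exclusion_documented_at = "dttm"
    ),
    diagnoses = c(patient_id = "chr", icd10 = "chr", onset_date = "date"),
    labs = c(
      patient_id = "chr", analyte = "chr", value = "dbl",
      collected_at = "dttm"
    ),
    vitals = c(
      patient_id = "chr", kind = "chr", value = "dbl", observed_at = "dttm"
    ),
    bmi_observations = c(
      patient_id = "chr", observed_at = "dttm", bmi = "dbl"
    ),
    cases = c(
      case_id = "chr", patient_id = "chr", site = "chr",
      scheduled_start = "dttm", scheduled_duration_min = "dbl",
      service = "chr", procedure_name = "chr", cpt_codes = "chr",
      emergency = "lgl", airway_plan = "chr",
      planned_postop_intubation = "lgl",
      attending_id = "chr", crna_present = "lgl", resident_present = "lgl",
      delay_patient = "lgl", delay_scheduling = "lgl", delay_staff = "lgl",
      disposition = "chr",
      unexpected_icu_transfer = "lgl", reintubation = "lgl",
      pacu_los_min = "dbl", min_spo2 = "dbl", death = "lgl"
    ),
    meds = c(
      case_id = "chr", drug = "chr", source = "chr",
      administered_at = "dttm", ordered_via_bpa = "lgl"
    )
  )
}

ehr_enums <- function() {
  list(
    sex = c("female", "male", "other"),
    airway_plan = c("intubated_general", "non_intubated"),
    disposition = c("pacu", "icu_direct", "icu_unplanned_transfer", "floor"),
    drug = c("rocuronium", "sugammadex", "neostigmine", "other"),
    source = c("study_pathway", "standard_stock", "na"),
    analyte = c("hemoglobin_serum", "other"),
    kind = c("spo2")
  )
}

empty_table <- function(schema) {
  cols <- lapply(schema, function(tp) {
    switch(tp,
      chr = character(),
      lgl = logical(),
      dbl = double(),
      int = integer(),
      date = as.Date(character()),
      dttm = as.POSIXct(character(), tz = "UTC")
    )
  })
  tibble::as_tibble(cols)
}

#' Assemble an EHR-style dataset
#'
#' Bundles the seven interchange tables (patients, diagnoses, labs, vitals,
#' BMI observations, surgical cases, medication administrations) into a
#' validated container. Any table may be omitted and defaults to an empty
#' table with the documented columns.
#'
#' @param patients,diagnoses,labs,vitals,bmi_observations,cases,meds Tibbles
#'   following the column dictionary (see `dataset_schema()`).
#' @param validate Run [validate_dataset()] (default `TRUE`).
#' @return An object of class `ehr_dataset`: a named list of tibbles.
#' @export
ehr_dataset <- function(patients = NULL, diagnoses = NULL, labs = NULL,
                        vitals = NULL, bmi_observations = NULL, cases = NULL,
                        meds = NULL, validate = TRUE) {
  sch <- ehr_schema()
  tabs <- list(
    patients = patients, diagnoses = diagnoses, labs = labs, vitals = vitals,
    bmi_observations = bmi_observations, cases = cases, meds = meds
  )
  tabs <- lapply(names(sch), function(nm) {
    tb <- tabs[[nm]]
    if (is.null(tb)) {
      return(empty_table(sch[[nm]]))
    }
    tb <- tibble::as_tibble(tb)
    missing <- setdiff(names(sch[[nm]]), names(tb))
    if (length(missing)) {
      stop(
        "table '", nm, "' is missing column(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    tb[names(sch[[nm]])]
  })
  names(tabs) <- names(sch)
  out <- structure(tabs, class = "ehr_dataset")
  if (validate) validate_dataset(out)
  out
}

#' Validate an EHR dataset
#'
#' Checks column types, enum values, record-level invariants (BMI > 0, SpO2
#' in 0-100, positive durations, study-pathway medications are BPA-ordered
#' sugammadex, PACU length of stay absent for direct ICU admissions, unique
#' identifiers) and referential integrity (every fact's `patient_id` and
#' every med's `case_id` must resolve). Referential breaks are hard errors
#' naming the offending identifiers.
#'
#' @param data An `ehr_dataset`.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(data) {
  stopifnot(inherits(data, "ehr_dataset"))
  sch <- ehr_schema()
  enums <- ehr_enums()
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  for (nm in names(sch)) {
    tb <- data[[nm]]
    for (col in names(sch[[nm]])) {
      tp <- sch[[nm]][[col]]
      v <- tb[[col]]
      ok <- switch(tp,
        chr = is.character(v),
        lgl = is.logical(v),
        dbl = is.numeric(v),
        int = is.numeric(v),
        date = inherits(v, "Date"),
        dttm = inherits(v, "POSIXct")
      )
      if (!ok) add(sprintf("%s$%s: expected %s", nm, col, tp))
    }
  }
  if (length(problems)) {
    stop("invalid dataset:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }

  p <- data$patients
  cs <- data$cases
  if (anyDuplicated(p$patient_id)) {
    add(sprintf(
      "duplicated patient_id: %s",
      paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(cs$case_id)) {
    add(sprintf(
      "duplicated case_id: %s",
      paste(unique(cs$case_id[duplicated(cs$case_id)]), collapse = ", ")
    ))
  }
  check_enum <- function(tab, col, allowed) {
    v <- data[[tab]][[col]]
    bad <- !is.na(v) & !(v %in% allowed)
    if (any(bad)) {
      add(sprintf(
        "%s$%s: invalid value(s) %s", tab, col,
        paste(unique(v[bad]), collapse = ", ")
      ))
    }
  }
  check_enum("patients", "sex", enums$sex)
  check_enum("cases", "airway_plan", enums$airway_plan)
  check_enum("cases", "disposition", enums$disposition)
  check_enum("meds", "drug", enums$drug)
  check_enum("meds", "source", enums$source)
  check_enum("labs", "analyte", enums$analyte)
  check_enum("vitals", "kind", enums$kind)

  if (any(!is.na(data$vitals$value) &
    (data$vitals$value < 0 | data$vitals$value > 100))) {
    add("vitals$value outside [0, 100]")
  }
  if (any(!is.na(data$bmi_observations$bmi) & data$bmi_observations$bmi <= 0)) {
    add("bmi_observations$bmi must be > 0")
  }
  if (nrow(cs) && any(!is.na(cs$scheduled_duration_min) &
    cs$scheduled_duration_min <= 0)) {
    add("cases$scheduled_duration_min must be > 0")
  }
  if (nrow(cs)) {
    bad <- cs$disposition == "icu_direct" & !is.na(cs$pacu_los_min)
    if (any(bad)) {
      add(sprintf(
        "pacu_los_min present for direct-ICU case(s): %s",
        paste(cs$case_id[bad], collapse = ", ")
      ))
    }
  }
  m <- data$meds
  if (nrow(m)) {
    bad <- m$source == "study_pathway" &
      (m$drug != "sugammadex" | !m$ordered_via_bpa)
    if (any(bad)) {
      add(sprintf(
        "study_pathway med must be BPA-ordered sugammadex (case %s)",
        paste(unique(m$case_id[bad]), collapse = ", ")
      ))
    }
  }

  # referential integrity
  ref <- function(tab, col, universe, what) {
    v <- data[[tab]][[col]]
    bad <- !(v %in% universe)
    if (any(bad)) {
      add(sprintf(
        "%s: dangling %s in %s: %s", tab, what, col,
        paste(unique(v[bad]), collapse = ", ")
      ))
    }
  }
  ref("diagnoses", "patient_id", p$patient_id, "patient_id")
  ref("labs", "patient_id", p$patient_id, "patient_id")
  ref("vitals", "patient_id", p$patient_id, "patient_id")
  ref("bmi_observations", "patient_id", p$patient_id, "patient_id")
  ref("cases", "patient_id", p$patient_id, "patient_id")
  ref("meds", "case_id", cs$case_id, "case_id")

  if (length(problems)) {
    stop("invalid dataset:\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  invisible(data)
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' The interchange column dictionary
#'
#' @return Named list: for each table, a named character vector mapping column
#'   name to type (`chr`, `lgl`, `dbl`, `int`, `date`, `dttm`).
#' @export
dataset_schema <- function() ehr_schema()

fmt_dttm <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parse_dttm <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# serialize a table to plain character columns per the schema
serialize_table <- function(tb, schema) {
  out <- tb
  for (col in names(schema)) {
    out[[col]] <- switch(schema[[col]],
      dttm = fmt_dttm(tb[[col]]),
      date = format(tb[[col]], "%Y-%m-%d"),
      tb[[col]]
    )
  }
  out
}

deserialize_table <- function(tb, schema, table_name) {
  missing <- setdiff(names(schema), names(tb))
  if (length(missing)) {
    stop(
      "table '", table_name, "' is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tb[names(schema)]
  for (col in names(schema)) {
    v <- out[[col]]
    parsed <- switch(schema[[col]],
      chr = as.character(v),
      lgl = if (is.logical(v)) v else as.logical(toupper(as.character(v))),
      dbl = if (is.numeric(v)) as.double(v) else as.double(v),
      int = as.integer(v),
      date = if (inherits(v, "Date")) v else as.Date(as.character(v)),
      dttm = if (inherits(v, "POSIXct")) {
        as.POSIXct(fmt_dttm(v), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      } else {
        parse_dttm(as.character(v))
      }
    )
    newly_na <- is.na(parsed) & !is.na(v) & as.character(v) != ""
    if (any(newly_na)) {
      stop(sprintf(
        "table '%s', column '%s': %d unparseable value(s), e.g. row %d ('%s')",
        table_name, col, sum(newly_na), which(newly_na)[1],
        as.character(v)[which(newly_na)[1]]
      ), call. = FALSE)
    }
    out[[col]] <- parsed
  }
  tibble::as_tibble(out)
}

#' Write a dataset to disk
#'
#' Emits one file per table (`patients`, `diagnoses`, `labs`, `vitals`,
#' `bmi_observations`, `cases`, `meds`) in the chosen format: RFC-4180 CSV
#' (UTF-8, header row) or JSONL (one record per line). Timestamps are written
#' as `YYYY-MM-DDTHH:MM:SS`, dates as `YYYY-MM-DD`.
#'
#' @param data An `ehr_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"jsonl"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "ehr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- ehr_schema()
  for (nm in names(sch)) {
    tb <- serialize_table(data[[nm]], sch[[nm]])
    path <- file.path(dir, paste0(nm, ".", format))
    if (format == "csv") {
      readr::write_csv(tb, path, na = "")
    } else {
      lines <- if (nrow(tb)) {
        vapply(seq_len(nrow(tb)), function(i) {
          jsonlite::toJSON(as.list(tb[i, ]),
            auto_unbox = TRUE, na = "null", digits = NA
          )
        }, character(1))
      } else {
        character()
      }
      writeLines(lines, path, useBytes = TRUE)
    }
  }
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Reads the table files written by [write_dataset()] (or produced externally
#' to the same column dictionary), coerces every column to its documented
#' type with per-row diagnostics on unparseable values, and validates the
#' result — referential breaks (e.g. a case referencing an unknown patient)
#' are hard errors naming the offending id. Missing table files are treated
#' as empty tables.
#'
#' @param dir Directory containing the table files.
#' @param format `"csv"` or `"jsonl"`.
#' @return A validated `ehr_dataset`.
#' @export
read_dataset <- function(dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    stop("dataset directory does not exist: '", dir, "'", call. = FALSE)
  }
  sch <- ehr_schema()
  tabs <- lapply(names(sch), function(nm) {
    path <- file.path(dir, paste0(nm, ".", format))
    if (!file.exists(path)) {
      return(empty_table(sch[[nm]]))
    }
    raw <- if (format == "csv") {
      readr::read_csv(path,
        col_types = readr::cols(.default = readr::col_character()),
        na = character(), progress = FALSE
      )
    } else {
      lines <- readLines(path, encoding = "UTF-8")
      lines <- lines[nzchar(lines)]
      if (!length(lines)) {
        return(empty_table(sch[[nm]]))
      }
      rows <- lapply(lines, function(l) {
        rec <- jsonlite::fromJSON(l)
        rec[vapply(rec, is.null, logical(1))] <- NA
        tibble::as_tibble(rec)
      })
      dplyr::bind_rows(rows)
    }
    if (format == "csv" && nrow(raw)) {
      # empty string means NA for non-character columns; keep "" for chr
      for (col in names(sch[[nm]])) {
        if (col %in% names(raw) && sch[[nm]][[col]] != "chr") {
          raw[[col]][raw[[col]] == ""] <- NA
        }
      }
    }
    deserialize_table(raw, sch[[nm]], nm)
  })
  names(tabs) <- names(sch)
  ehr_dataset(
    patients = tabs$patients, diagnoses = tabs$diagnoses, labs = tabs$labs,
    vitals = tabs$vitals, bmi_observations = tabs$bmi_observations,
    cases = tabs$cases, meds = tabs$meds
  )
}

# semicolon-separated list columns (allergies, cpt_codes)
split_list_col <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}
join_list_col <- function(lst) {
  vapply(lst, paste, character(1), collapse = ";")
}
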
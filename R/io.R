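#' Assemble a cohort from event-log tables
#'
#' Bundles the four routine-record tables — patient intake, clinic visits,
#' pharmacy dispensings (one row per drug component), and CD4 tests — into a
#' validated `cohort_data` object. Every event must reference an existing
#' patient; dates are `Date`s (day precision).
#'
#' @param patients,visits,dispensings,cd4_tests Data frames with the columns
#'   documented in [read_cohort()].
#' @param rejects Optional tibble of malformed rows (from [read_cohort()]).
#' @return A `cohort_data` object: a list of the four tibbles, each sorted by
#'   patient and date, with any `rejects` attached as an attribute.
#' @export
cohort_data <- function(patients, visits, dispensings, cd4_tests,
                        rejects = NULL) {
  patients <- tibble::as_tibble(patients)
  visits <- tibble::as_tibble(visits)
  dispensings <- tibble::as_tibble(dispensings)
  cd4_tests <- tibble::as_tibble(cd4_tests)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("%s is missing mandatory column(s): %s",
                    what, paste(miss, collapse = ", ")))
    }
  }
  need(patients, c("patient_id", "gender", "age_years", "initiation_date",
                   "baseline_weight_kg", "baseline_cd4", "selfreport_scale",
                   "data_collection_date"), "patients")
  need(visits, c("patient_id", "actual_date"), "visits")
  need(dispensings, c("patient_id", "dispense_date", "days_of_supply"),
       "dispensings")
  need(cd4_tests, c("patient_id", "test_date", "count"), "cd4_tests")

  if (anyDuplicated(patients$patient_id)) abort("duplicate patient_id in patients")
  for (tab in list(visits = visits, dispensings = dispensings,
                   cd4_tests = cd4_tests)) {
    orphan <- setdiff(tab$patient_id, patients$patient_id)
    if (length(orphan)) {
      abort(sprintf("events reference unknown patient(s): %s",
                    paste(head(orphan, 5), collapse = ", ")))
    }
  }
  if (nrow(dispensings) && any(dispensings$days_of_supply < 1, na.rm = TRUE)) {
    abort("days_of_supply must be >= 1 for every dispensed component")
  }
  if (nrow(cd4_tests) && any(cd4_tests$count < 0, na.rm = TRUE)) {
    abort("CD4 counts must be non-negative")
  }

  structure(
    list(
      patients = dplyr::arrange(patients, .data$patient_id),
      visits = dplyr::arrange(visits, .data$patient_id, .data$actual_date),
      dispensings = dplyr::arrange(dispensings, .data$patient_id,
                                   .data$dispense_date,
                                   dplyr::pick(dplyr::any_of("drug_code"))),
      cd4_tests = dplyr::arrange(cd4_tests, .data$patient_id, .data$test_date)
    ),
    rejects = rejects %||% empty_rejects(),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", nrow(x$patients), "patients |",
      nrow(x$visits), "visits |", nrow(x$dispensings), "dispensing rows |",
      nrow(x$cd4_tests), "CD4 tests\n")
  nr <- nrow(attr(x, "rejects"))
  if (nr) cat("  ", nr, "rejected input row(s); see cohort_rejects()\n")
  invisible(x)
}

#' Rejected rows from the last read
#'
#' @param cohort A `cohort_data`.
#' @return Tibble with columns `file`, `row`, `reason`.
#' @export
cohort_rejects <- function(cohort) attr(cohort, "rejects") %||% empty_rejects()

empty_rejects <- function() {
  tibble::tibble(file = character(), row = integer(), reason = character())
}

cohort_files <- c(patients = "patients.csv", visits = "visits.csv",
                  dispensings = "dispensings.csv", cd4_tests = "cd4.csv")

# column dictionary: name -> type (d = Date, i = integer, n = numeric,
# l = logical, c = character). Dates are ISO-8601; empty field = absent.
cohort_dictionary <- list(
  patients = c(patient_id = "c", gender = "c", age_years = "i", age_band = "c",
               married = "l", education = "c", occupation = "c", living = "c",
               support_partner = "l", facility_id = "i",
               facility_management = "c", location = "c", who_stage = "i",
               tb_at_initiation = "l", pmtct_history = "l",
               prior_art_exposure = "l", initiation_date = "d",
               baseline_weight_kg = "n", baseline_cd4 = "i",
               baseline_cd4_date = "d", data_collection_date = "d",
               selfreport_scale = "c"),
  visits = c(patient_id = "c", actual_date = "d", scheduled_date = "d",
             weight_kg = "n", selfreport_code = "i", regimen_id = "c",
             side_effect_or_oi_flag = "l"),
  dispensings = c(patient_id = "c", dispense_date = "d", drug_code = "c",
                  days_of_supply = "i", regimen_id = "c", contains_pi = "l"),
  cd4_tests = c(patient_id = "c", test_date = "d", count = "i")
)

#' Read a cohort from delimited event-log files
#'
#' Reads the four comma-delimited files of the documented dialect
#' (`patients.csv`, `visits.csv`, `dispensings.csv`, `cd4.csv`; ISO-8601
#' dates, UTF-8, mandatory header row) from a directory. Rows whose dates or
#' numbers cannot be parsed are collected into a rejects report — retrievable
#' with [cohort_rejects()] — rather than silently dropped. A missing mandatory
#' column is a hard error naming the column.
#'
#' @param path Directory containing the four files, or a named character
#'   vector with entries `patients`, `visits`, `dispensings`, `cd4_tests`.
#' @return A [cohort_data()] with a `rejects` attribute.
#' @export
read_cohort <- function(path) {
  paths <- if (length(path) == 1L && is.null(names(path))) {
    setNames(file.path(path, cohort_files), names(cohort_files))
  } else {
    path
  }
  miss <- setdiff(names(cohort_files), names(paths))
  if (length(miss)) abort(paste("no path given for:", paste(miss, collapse = ", ")))
  for (p in paths) if (!file.exists(p)) abort(paste("file not found:", p))

  rejects <- empty_rejects()
  tabs <- list()
  for (tab in names(cohort_files)) {
    dict <- cohort_dictionary[[tab]]
    raw <- readr::read_csv(paths[[tab]], col_types = readr::cols(.default = "c"),
                           na = "", progress = FALSE)
    missing_cols <- setdiff(names(dict), names(raw))
    if (length(missing_cols)) {
      abort(sprintf("%s: missing mandatory column(s): %s", basename(paths[[tab]]),
                    paste(missing_cols, collapse = ", ")))
    }
    parsed <- raw
    bad <- rep(FALSE, nrow(raw))
    why <- rep(NA_character_, nrow(raw))
    for (col in names(dict)) {
      x <- raw[[col]]
      y <- switch(dict[[col]],
        d = {
          # strict ISO-8601: strptime alone accepts garbage like "31-02-2007"
          z <- as.Date(x, format = "%Y-%m-%d")
          z[!is.na(z) & format(z, "%Y-%m-%d") != x] <- NA
          z
        },
        i = suppressWarnings(as.integer(x)),
        n = suppressWarnings(as.numeric(x)),
        l = as.logical(x),
        c = x
      )
      newly <- !is.na(x) & is.na(y) & !bad
      if (any(newly)) {
        why[newly] <- sprintf("bad %s in column %s",
                              switch(dict[[col]], d = "date", l = "logical", "value"),
                              col)
        bad <- bad | newly
      }
      parsed[[col]] <- y
    }
    if (any(bad)) {
      rejects <- dplyr::bind_rows(rejects, tibble::tibble(
        file = basename(paths[[tab]]), row = which(bad), reason = why[bad]
      ))
    }
    tabs[[tab]] <- parsed[!bad, names(dict)]
  }

  cohort_data(tabs$patients, tabs$visits, tabs$dispensings, tabs$cd4_tests,
              rejects = rejects)
}

#' Write a cohort to delimited event-log files
#'
#' Writes the dialect that [read_cohort()] reads: comma-delimited, ISO-8601
#' dates, header row, absent values as empty fields, rows in deterministic
#' (patient, date) order. Round trips exactly.
#'
#' @param cohort A [cohort_data()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste("cannot create directory:", out_dir))
  }
  paths <- setNames(file.path(out_dir, cohort_files), names(cohort_files))
  for (tab in names(cohort_files)) {
    df <- cohort[[tab]][, names(cohort_dictionary[[tab]])]
    readr::write_csv(df, paths[[tab]], na = "", progress = FALSE)
  }
  invisible(paths)
}
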
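#' Screen a cohort against the study inclusion criteria
#'
#' Classifies every patient against the inclusion criteria, applied in fixed
#' order; exclusion is attributed to the *first* failed criterion:
#'
#' 1. `age` — at least 18 years old at initiation;
#' 2. `prior_art` — no previous ART exposure (PMTCT does not count);
#' 3. `visit_continuity` — at least one clinic visit in each of the first two
#'    consecutive 3-month periods after initiation (days 1-91 and 92-182;
#'    initiation day is day 0);
#' 4. `selfreport_availability` — at least one recorded adherence self-report
#'    in those two quarters;
#' 5. `dispensing_data` — regimen and quantity-dispensed data available during
#'    follow-up;
#' 6. `cd4_availability` — a CD4 count within 3 months (91 days) before
#'    initiation and at least one in the 18 months after.
#'
#' Screening never fails: unclassifiable data counts as failing the relevant
#' criterion. The result is deterministic and independent of input row order.
#'
#' @param cohort A [cohort_data()].
#' @param asof_months Length of the continuity window in months (default 6,
#'   split into two 91-day quarters).
#' @return An `eligibility_report`: list with `included` (character ids),
#'   `excluded` (tibble of `patient_id`, `reason`), `fractions` (tibble of
#'   per-criterion exclusion fractions over all screened patients), and
#'   `n_screened`. [tidy()] returns the per-patient classification.
#' @export
screen_eligibility <- function(cohort, asof_months = 6L) {
  stopifnot(inherits(cohort, "cohort_data"))
  half <- as.integer(round(asof_months * 30.4167 / 2)) # 91 days for 6 months
  p <- cohort$patients

  vis <- dplyr::left_join(cohort$visits,
                          p[, c("patient_id", "initiation_date")],
                          by = "patient_id") |>
    dplyr::mutate(day = days_since(.data$actual_date, .data$initiation_date))
  disp <- dplyr::left_join(cohort$dispensings,
                           p[, c("patient_id", "initiation_date")],
                           by = "patient_id") |>
    dplyr::mutate(day = days_since(.data$dispense_date, .data$initiation_date))
  cd4 <- dplyr::left_join(cohort$cd4_tests,
                          p[, c("patient_id", "initiation_date")],
                          by = "patient_id") |>
    dplyr::mutate(day = days_since(.data$test_date, .data$initiation_date))

  q1 <- vis |> dplyr::filter(.data$day >= 1, .data$day <= half) |>
    dplyr::distinct(.data$patient_id)
  q2 <- vis |> dplyr::filter(.data$day > half, .data$day <= 2L * half) |>
    dplyr::distinct(.data$patient_id)
  sr <- vis |> dplyr::filter(.data$day >= 1, .data$day <= 2L * half,
                             !is.na(.data$selfreport_code)) |>
    dplyr::distinct(.data$patient_id)
  dd <- disp |> dplyr::filter(!is.na(.data$days_of_supply),
                              .data$day >= 0, .data$day <= 548) |>
    dplyr::distinct(.data$patient_id)
  cd4_pre <- cd4 |> dplyr::filter(.data$day >= -91, .data$day <= 0) |>
    dplyr::distinct(.data$patient_id)
  cd4_post <- cd4 |> dplyr::filter(.data$day > 0, .data$day <= 548) |>
    dplyr::distinct(.data$patient_id)

  ok_age <- !is.na(p$age_years) & p$age_years >= 18
  ok_art <- !is.na(p$prior_art_exposure) & !p$prior_art_exposure
  ok_vis <- p$patient_id %in% q1$patient_id & p$patient_id %in% q2$patient_id
  ok_sr <- p$patient_id %in% sr$patient_id
  ok_disp <- p$patient_id %in% dd$patient_id
  ok_cd4 <- p$patient_id %in% cd4_pre$patient_id &
    p$patient_id %in% cd4_post$patient_id

  crit <- c("age", "prior_art", "visit_continuity",
            "selfreport_availability", "dispensing_data", "cd4_availability")
  ok <- cbind(ok_age, ok_art, ok_vis, ok_sr, ok_disp, ok_cd4)
  colnames(ok) <- crit
  first_fail <- apply(ok, 1L, function(r) {
    w <- which(!r)
    if (length(w)) crit[w[1]] else NA_character_
  })

  excluded <- tibble::tibble(patient_id = p$patient_id, reason = first_fail) |>
    dplyr::filter(!is.na(.data$reason))
  n <- nrow(p)
  fractions <- tibble::tibble(
    criterion = crit,
    n_failed = colSums(!ok),
    fraction = if (n) colSums(!ok) / n else rep(NA_real_, length(crit))
  )

  structure(
    list(included = setdiff(p$patient_id, excluded$patient_id),
         excluded = excluded, fractions = fractions, n_screened = n),
    class = "eligibility_report"
  )
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("<eligibility_report>", length(x$included), "included /",
      nrow(x$excluded), "excluded of", x$n_screened, "screened\n")
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    for (nm in names(tab)) cat("  ", nm, ":", tab[[nm]], "\n")
  }
  invisible(x)
}

#' @rdname screen_eligibility
#' @param x An `eligibility_report`.
#' @param ... Unused.
#' @method tidy eligibility_report
#' @export
tidy.eligibility_report <- function(x, ...) {
  tibble::tibble(
    patient_id = c(x$included, x$excluded$patient_id),
    eligible = rep(c(TRUE, FALSE), c(length(x$included), nrow(x$excluded))),
    reason = c(rep(NA_character_, length(x$included)), x$excluded$reason)
  ) |> dplyr::arrange(.data$patient_id)
}
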
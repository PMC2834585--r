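#' Average self-reported adherence to date
#'
#' Arithmetic mean of the recorded self-report codes (1 = perfect, 2 = good,
#' 3 = poor) at visits up to and including `asof`. Intended for patients on
#' the 3-level reporting scale; patients from facilities recording 2-level
#' reports are excluded from self-report analyses upstream.
#'
#' @param visits Tibble of one patient's visits (`actual_date`,
#'   `selfreport_code`).
#' @param asof Date; visits with `actual_date <= asof` contribute.
#' @return Mean code in `[1, 3]`, or `NA` if no codes recorded by `asof`.
#' @export
avg_selfreport <- function(visits, asof) {
  codes <- selfreport_codes(visits, asof)
  if (!length(codes)) return(NA_real_)
  mean(codes)
}

#' Self-report flags to date
#'
#' @inheritParams avg_selfreport
#' @return Named logical vector: `any_poor` (ever coded 3) and
#'   `any_imperfect` (ever coded worse than 1). Both `NA` if no codes.
#' @export
selfreport_flags <- function(visits, asof) {
  codes <- selfreport_codes(visits, asof)
  if (!length(codes)) return(c(any_poor = NA, any_imperfect = NA))
  c(any_poor = any(codes == 3), any_imperfect = any(codes > 1))
}

selfreport_codes <- function(visits, asof) {
  codes <- visits$selfreport_code[visits$actual_date <= asof]
  codes <- codes[!is.na(codes)]
  if (length(codes) && any(!codes %in% 1:3)) {
    abort("self-report codes must be 1 (perfect), 2 (good) or 3 (poor)")
  }
  codes
}

#' Appointment-keeping percentages to date
#'
#' Over visits with a recorded scheduled date and `actual_date <= asof`:
#' the percentage attended on or before the scheduled date, and the
#' percentage attended within 3 days after it (both over the same
#' denominator, so the within-3-days percentage can never be smaller).
#' Visits without a scheduled date are excluded, not imputed.
#'
#' @param visits Tibble with `actual_date`, `scheduled_date`.
#' @param asof Date.
#' @return Tibble with `pct_on_or_before`, `pct_within_3d`, `n_scheduled`;
#'   percentages `NA` when no visit has a scheduled date.
#' @export
visit_timeliness <- function(visits, asof) {
  v <- visits[visits$actual_date <= asof & !is.na(visits$scheduled_date), ]
  n <- nrow(v)
  if (!n) {
    return(tibble::tibble(pct_on_or_before = NA_real_, pct_within_3d = NA_real_,
                          n_scheduled = 0L))
  }
  tibble::tibble(
    pct_on_or_before = 100 * sum(v$actual_date <= v$scheduled_date) / n,
    pct_within_3d = 100 * sum(v$actual_date <= v$scheduled_date + 3) / n,
    n_scheduled = n
  )
}

#' Percent of visits before supply exhaustion
#'
#' For each visit after the first, the visit is timely iff it occurred on or
#' before the expected finish date of the medicines dispensed at the
#' *previous* visit (previous dispensing date + its days of supply).
#' Deliberately ignores carryover from earlier visits — this indicator is a
#' schedule-free attendance proxy and is known to overstate how often
#' patients run out. Visit pairs whose previous visit has no dispensing are
#' excluded from the denominator.
#'
#' @param visits Tibble with `actual_date`.
#' @param dispensings Tibble with `dispense_date`, `days_of_supply` and
#'   optionally `drug_code` (effective supply = minimum across components).
#' @param asof Date.
#' @return Percent over visits after the first, or `NA` if no valid pairs.
#' @export
pct_visits_before_exhaustion <- function(visits, dispensings, asof) {
  v <- visits[visits$actual_date <= asof, ]
  v <- v[order(v$actual_date), ]
  if (nrow(v) < 2L) return(NA_real_)
  eff <- effective_supply(dplyr::mutate(
    dispensings, patient_id = dispensings$patient_id %||% "patient"
  ))
  sup <- eff$supply[match(v$actual_date, eff$dispense_date)]
  prev_date <- v$actual_date[-nrow(v)]
  prev_sup <- sup[-nrow(v)]
  cur_date <- v$actual_date[-1L]
  valid <- !is.na(prev_sup)
  if (!any(valid)) return(NA_real_)
  timely <- cur_date[valid] <= prev_date[valid] + prev_sup[valid]
  100 * sum(timely) / sum(valid)
}

#' Select the index visit
#'
#' The follow-up visit whose actual date is nearest to `target_day` days
#' after initiation; an equidistant tie goes to the earlier visit.
#'
#' @param visits Tibble of one patient's visits (`actual_date`).
#' @param initiation Initiation date.
#' @param target_day Target day since initiation (default 180).
#' @return The selected visit date.
#' @export
select_index_visit <- function(visits, initiation, target_day = 180L) {
  if (!nrow(visits)) abort("patient has no visits")
  d <- days_since(visits$actual_date, initiation)
  initiation + nearest_day(d, target_day)
}

table2_bands <- c("<80%", "80% to <85%", "85% to <90%", "90% to <95%",
                  "95% to <100%", "100%")
model_bands <- c("<80%", "80% to <90%", "90% to <100%", "100%")

#' Categorize percent of days covered into report or model bands
#'
#' Bands are half-open, upper-exclusive, except the exact-100 band:
#' the `"table2"` scheme uses `<80`, `[80,85)`, `[85,90)`, `[90,95)`,
#' `[95,100)`, `100`; the `"model"` scheme (regression reference = `"100%"`)
#' uses `<80`, `[80,90)`, `[90,100)`, `100`.
#'
#' @param pct Numeric vector of percentages in `[0, 100]`.
#' @param scheme `"table2"` or `"model"`.
#' @return Factor with the scheme's band labels.
#' @export
categorize_coverage <- function(pct, scheme = c("table2", "model")) {
  scheme <- match.arg(scheme)
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) {
    abort("`pct` must lie in [0, 100]")
  }
  breaks <- if (scheme == "table2") c(-Inf, 80, 85, 90, 95, 100, Inf) else
    c(-Inf, 80, 90, 100, Inf)
  labels <- if (scheme == "table2") table2_bands else model_bands
  cut(pct, breaks = breaks, labels = labels, right = FALSE)
}
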
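# Dispensing-based coverage: supply accumulates into a pool on each dispensing
# day (carryover of unfinished supply from early refills), one unit is consumed
# per day while the pool is positive, and day d is covered iff the pool is
# positive entering day d. The closed-form interval recursion below is
# equivalent to that day-by-day pool simulation:
#   E_j = max(E_{j-1}, d_j) + s_j   (coverage-end day after dispensing j)
#   g_j = max(0, d_j - E_{j-1})     (uncovered run closed by dispensing j)

# state from effective dispensings (days sorted ascending, supplies >= 1);
# returns leading-zero-padded vectors for O(1) lookup at any as-of day
coverage_state <- function(days, supplies) {
  j <- length(days)
  E <- numeric(j + 1L)
  g <- numeric(j + 1L)
  for (k in seq_len(j)) {
    g[k + 1L] <- max(0, days[k] - E[k])
    E[k + 1L] <- max(E[k], days[k]) + supplies[k]
  }
  list(days = days, E = E, g = g, cumg = cumsum(g), cmaxg = cummax(g))
}

# uncovered days and longest uncovered run in [0, t) for each t (vectorized)
coverage_at <- function(state, t) {
  k <- findInterval(t - 1L, state$days) + 1L # index into padded vectors
  open_gap <- pmax(0, t - state$E[k])
  list(
    uncovered = state$cumg[k] + open_gap,
    longest_gap = pmax(state$cmaxg[k], open_gap)
  )
}

# collapse per-component dispensing rows to one effective supply per
# (patient, day): same-drug rows on a day sum, different drugs take the
# minimum (therapy is covered only while all components are on hand)
effective_supply <- function(dispensings) {
  df <- dispensings
  if (!"drug_code" %in% names(df)) df$drug_code <- "drug"
  dt <- data.table::as.data.table(
    df[, c("patient_id", "dispense_date", "drug_code", "days_of_supply")]
  )
  if (nrow(dt) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          dispense_date = as.Date(character()),
                          supply = numeric()))
  }
  s <- dt[, list(days_of_supply = sum(days_of_supply)),
          by = c("patient_id", "dispense_date", "drug_code")]
  s <- s[, list(supply = min(days_of_supply)),
         by = c("patient_id", "dispense_date")]
  data.table::setorderv(s, c("patient_id", "dispense_date"))
  tibble::as_tibble(s)
}

#' Build a medicine-coverage timeline for one patient
#'
#' Converts a patient's dispensing history into the covered-day intervals of
#' the observation window `[0, asof)` (day 0 = initiation date, half-open at
#' `asof`), assuming one day of supply consumed per day and carryover of
#' unfinished supply from early refills.
#'
#' @param dispensings Tibble of this patient's dispensing rows
#'   (`dispense_date`, `days_of_supply`, optionally `drug_code` for
#'   multi-component regimens, whose effective supply is the per-day minimum
#'   across components).
#' @param initiation Initiation date (day 0).
#' @param asof End of the observation window (exclusive); must be after
#'   `initiation`. Dispensings on or after `asof` are ignored with a note.
#' @return A `coverage_timeline`: list with `intervals` (tibble of
#'   `start_day`, `end_day`, half-open, clipped to the window),
#'   `window_end_day`, `supply_pool_trace` (pool remaining after each
#'   dispensing), and `notes`.
#' @examples
#' d <- tibble::tibble(
#'   dispense_date = as.Date("2007-01-01") + c(0, 45),
#'   days_of_supply = c(30, 30)
#' )
#' tl <- build_coverage_timeline(d, as.Date("2007-01-01"),
#'                               as.Date("2007-01-01") + 90)
#' pct_days_covered(tl)
#' @export
build_coverage_timeline <- function(dispensings, initiation, asof) {
  if (!inherits(asof, "Date")) asof <- as.Date(asof)
  if (!inherits(initiation, "Date")) initiation <- as.Date(initiation)
  W <- days_since(asof, initiation)
  if (is.na(W) || W < 1L) abort("`asof` must be after `initiation`")

  eff <- effective_supply(dplyr::mutate(
    dispensings,
    patient_id = dispensings$patient_id %||% "patient"
  ))
  day <- days_since(eff$dispense_date, initiation)
  if (any(day < 0L)) abort("dispensing before initiation date")
  notes <- character()
  late <- day >= W
  if (any(late)) {
    notes <- sprintf("%d dispensing(s) on/after the as-of day ignored", sum(late))
  }
  ord <- order(day[!late])
  st <- coverage_state(day[!late][ord], eff$supply[!late][ord])

  # covered intervals [max(E_{j-1}, d_j) - s_j ... ]: a dispensing either opens
  # a new interval at d_j (if a gap preceded) or extends the current one
  d <- st$days
  E <- st$E
  if (length(d)) {
    opens <- which(st$g[-1L] > 0 | seq_along(d) == 1L)
    start <- d[opens]
    end <- c(E[opens[-1L]], E[length(E)])
    keep <- start < W
    intervals <- tibble::tibble(start_day = start[keep],
                                end_day = pmin(end[keep], W))
  } else {
    intervals <- tibble::tibble(start_day = integer(), end_day = integer())
  }
  structure(
    list(
      intervals = intervals,
      window_end_day = W,
      supply_pool_trace = tibble::tibble(day = d, pool_after = E[-1L] - d),
      notes = notes,
      state = st
    ),
    class = "coverage_timeline"
  )
}

#' @export
print.coverage_timeline <- function(x, ...) {
  cat("<coverage_timeline> window [0,", x$window_end_day, ") days;",
      nrow(x$intervals), "covered interval(s);",
      round(pct_days_covered(x), 1), "% of days covered\n")
  invisible(x)
}

#' Percent of days covered
#'
#' 100 x covered days / window length for a [build_coverage_timeline()];
#' oversupply never pushes it above 100.
#'
#' @param timeline A `coverage_timeline`.
#' @return Percent in `[0, 100]`.
#' @export
pct_days_covered <- function(timeline) {
  stopifnot(inherits(timeline, "coverage_timeline"))
  W <- timeline$window_end_day
  if (W < 1L) abort("empty observation window")
  100 * sum(timeline$intervals$end_day - timeline$intervals$start_day) / W
}

#' Longest treatment gap
#'
#' Length in days of the longest maximal run of consecutive uncovered days in
#' the observation window. Uncovered days after the last dispensed supply up
#' to the as-of day count: a patient who stops refilling accrues a gap.
#'
#' @param timeline A `coverage_timeline`.
#' @return Integer number of days (0 if fully covered).
#' @export
longest_gap <- function(timeline) {
  stopifnot(inherits(timeline, "coverage_timeline"))
  iv <- timeline$intervals
  W <- timeline$window_end_day
  if (!nrow(iv)) return(as.integer(W))
  gaps <- c(iv$start_day[1], iv$start_day[-1L] - iv$end_day[-nrow(iv)],
            W - iv$end_day[nrow(iv)])
  as.integer(max(gaps, 0))
}

#' @rdname longest_gap
#' @param threshold Gap flag is `TRUE` iff the longest gap is *strictly*
#'   longer than this many days (default 30).
#' @export
gap_exceeds <- function(timeline, threshold = 30L) {
  longest_gap(timeline) > threshold
}
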
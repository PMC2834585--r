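# vectorized per-patient indicator engine: all eight measures, cumulatively
# from initiation, at any set of as-of days (day 0 = initiation; every window
# is [0, asof) half-open, so the as-of day's own dispensing does not count)

indicator_series <- function(visit_day, sched_day, code, disp_day, disp_supply,
                             asof_day) {
  ord <- order(visit_day)
  vd <- visit_day[ord]
  sd_ <- sched_day[ord]
  cd <- code[ord]
  t <- asof_day

  if (length(cd) && any(!is.na(cd) & !cd %in% 1:3)) {
    abort("self-report codes must be 1 (perfect), 2 (good) or 3 (poor)")
  }

  ## dispensing-based coverage
  dord <- order(disp_day)
  st <- coverage_state(disp_day[dord], disp_supply[dord])
  cv <- coverage_at(st, t)
  pct_cov <- 100 * (t - cv$uncovered) / t
  gap <- as.integer(cv$longest_gap)

  idx <- findInterval(t, vd) # visits with actual day <= asof

  ## self-reports
  has <- !is.na(cd)
  cn <- c(0L, cumsum(has))
  csum <- c(0, cumsum(ifelse(has, cd, 0L)))
  cpoor <- c(0L, cummax(as.integer(has & cd == 3L)))
  cimp <- c(0L, cummax(as.integer(has & cd > 1L)))
  n_sr <- cn[idx + 1L]
  avg_sr <- ifelse(n_sr > 0, csum[idx + 1L] / pmax(n_sr, 1L), NA_real_)
  any_poor <- ifelse(n_sr > 0, cpoor[idx + 1L] > 0L, NA)
  any_imp <- ifelse(n_sr > 0, cimp[idx + 1L] > 0L, NA)

  ## appointment keeping (visits without a scheduled date are excluded)
  hs <- !is.na(sd_)
  cden <- c(0L, cumsum(hs))
  con <- c(0L, cumsum(as.integer(hs & vd <= sd_)))
  cw3 <- c(0L, cumsum(as.integer(hs & vd <= sd_ + 3L)))
  den <- cden[idx + 1L]
  pct_on <- ifelse(den > 0, 100 * con[idx + 1L] / pmax(den, 1L), NA_real_)
  pct_w3 <- ifelse(den > 0, 100 * cw3[idx + 1L] / pmax(den, 1L), NA_real_)

  ## attendance before exhaustion of the previous visit's supply
  ## (no carryover, by definition)
  sup_at <- disp_supply[dord][match(vd, disp_day[dord])]
  nv <- length(vd)
  valid <- timely <- integer(nv)
  if (nv >= 2L) {
    valid[-1L] <- as.integer(!is.na(sup_at[-nv]))
    timely[-1L] <- as.integer(valid[-1L] == 1L &
                                vd[-1L] <= vd[-nv] + ifelse(is.na(sup_at[-nv]),
                                                            0L, sup_at[-nv]))
  }
  cvalid <- c(0L, cumsum(valid))
  ctimely <- c(0L, cumsum(timely))
  denx <- cvalid[idx + 1L]
  pct_ex <- ifelse(denx > 0, 100 * ctimely[idx + 1L] / pmax(denx, 1L), NA_real_)

  n_fup <- idx - findInterval(0L, vd) # follow-up visits (day >= 1) to date

  # low-overhead constructor: this runs once per patient in tight loops
  tibble::new_tibble(list(
    asof_day = as.integer(t),
    avg_selfreport = avg_sr,
    any_poor_selfreport = any_poor,
    any_imperfect_selfreport = any_imp,
    pct_days_covered = pct_cov,
    longest_gap_days = gap,
    gap_gt30 = gap > 30L,
    pct_visits_on_or_before = pct_on,
    pct_visits_within_3d = pct_w3,
    pct_visits_before_exhaustion = pct_ex,
    n_visits = as.integer(n_fup),
    n_selfreports = as.integer(n_sr)
  ), nrow = length(t))
}

# follow-up horizon: 18 calendar months ~ 548 days
FOLLOWUP_CAP_DAYS <- 548L

# per-patient prepared event lists keyed by patient_id
prep_events <- function(cohort) {
  p <- cohort$patients
  init <- setNames(p$initiation_date, p$patient_id)
  vis <- cohort$visits |>
    dplyr::mutate(
      day = days_since(.data$actual_date, init[.data$patient_id]),
      sched = days_since(.data$scheduled_date, init[.data$patient_id])
    )
  eff <- effective_supply(cohort$dispensings) |>
    dplyr::mutate(day = days_since(.data$dispense_date, init[.data$patient_id]))
  list(
    patients = p,
    visits = split(vis[, c("day", "sched", "selfreport_code", "weight_kg")],
                   factor(vis$patient_id, levels = p$patient_id)),
    disp = split(eff[, c("day", "supply")],
                 factor(eff$patient_id, levels = p$patient_id))
  )
}

#' Indicator snapshot for one patient at one as-of date
#'
#' Computes all eight adherence/attendance measures cumulatively from
#' initiation to `asof` (window `[0, asof)`, half-open). Patients on the
#' 2-level self-report scale get absent self-report fields. Snapshots are
#' refused before the first visit and beyond `min(18 months,
#' data_collection_date)`.
#'
#' @param cohort A [cohort_data()].
#' @param patient_id Patient identifier.
#' @param asof Date of the snapshot (normally a visit date).
#' @return One-row tibble of the `IndicatorSnapshot` fields.
#' @export
snapshot_at <- function(cohort, patient_id, asof) {
  stopifnot(inherits(cohort, "cohort_data"))
  p <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  if (!nrow(p)) abort(paste("unknown patient:", patient_id))
  asof <- as.Date(asof)
  t <- days_since(asof, p$initiation_date)
  cap <- min(FOLLOWUP_CAP_DAYS,
             days_since(p$data_collection_date, p$initiation_date))
  if (t > cap) {
    abort(sprintf("as-of day %d is beyond the observation horizon (day %d)",
                  t, cap))
  }
  vis <- cohort$visits[cohort$visits$patient_id == patient_id, ]
  if (!nrow(vis) || t < min(days_since(vis$actual_date, p$initiation_date))) {
    abort("`asof` precedes the patient's first recorded visit")
  }
  disp <- cohort$dispensings[cohort$dispensings$patient_id == patient_id, ]
  eff <- effective_supply(disp)
  out <- indicator_series(
    days_since(vis$actual_date, p$initiation_date),
    days_since(vis$scheduled_date, p$initiation_date),
    vis$selfreport_code,
    days_since(eff$dispense_date, p$initiation_date),
    eff$supply, t
  )
  out <- dplyr::mutate(out, patient_id = patient_id,
                       selfreport_scale = p$selfreport_scale, .before = 1L)
  mask_two_level(out)
}

mask_two_level <- function(snapshots) {
  if (!nrow(snapshots) || !"selfreport_scale" %in% names(snapshots)) {
    return(snapshots)
  }
  two <- snapshots$selfreport_scale == "two_level"
  snapshots$avg_selfreport[two] <- NA_real_
  snapshots$any_poor_selfreport[two] <- NA
  snapshots$any_imperfect_selfreport[two] <- NA
  snapshots
}

#' Indicator snapshots across a cohort
#'
#' Computes the eight-measure snapshot for every patient, either at the index
#' visit (the visit nearest `target_day` days after initiation, ties to the
#' earlier visit) or cumulatively at every follow-up visit. As-of days beyond
#' `min(18 months, data_collection_date)` or `max_day` are dropped.
#'
#' @param cohort A [cohort_data()].
#' @param at `"index"` (one row per patient) or `"visits"` (one row per
#'   follow-up visit).
#' @param target_day Index-visit target day (default 180).
#' @param max_day Optional upper bound on the as-of day (e.g. 270 for the
#'   weight-model panel).
#' @param include Optional character vector of patient ids (e.g. the
#'   `included` set of [screen_eligibility()]).
#' @return Tibble of snapshots with `patient_id`, `selfreport_scale`,
#'   `asof_day`, the measures, and `weight_kg` recorded at the as-of visit.
#' @export
cohort_snapshots <- function(cohort, at = c("index", "visits"),
                             target_day = 180L, max_day = NULL,
                             include = NULL) {
  at <- match.arg(at)
  stopifnot(inherits(cohort, "cohort_data"))
  pr <- prep_events(cohort)
  p <- pr$patients
  if (!is.null(include)) {
    sel <- p$patient_id %in% include
  } else {
    sel <- rep(TRUE, nrow(p))
  }
  cap <- pmin(FOLLOWUP_CAP_DAYS,
              days_since(p$data_collection_date, p$initiation_date))
  res <- vector("list", nrow(p))
  for (i in which(sel)) {
    v <- pr$visits[[i]]
    d <- pr$disp[[i]]
    fup <- v$day[v$day >= 1L & v$day <= cap[i]]
    if (!length(fup)) next
    t <- if (at == "index") nearest_day(fup, target_day) else fup
    if (!is.null(max_day)) t <- t[t <= max_day]
    if (!length(t)) next
    out <- indicator_series(v$day, v$sched, v$selfreport_code,
                            d$day, d$supply, t)
    out$patient_id <- p$patient_id[i]
    out$weight_kg <- v$weight_kg[match(t, v$day)]
    res[[i]] <- out
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    abort("no snapshots could be computed (no follow-up visits in window)")
  }
  out <- dplyr::left_join(out,
                          p[, c("patient_id", "selfreport_scale")],
                          by = "patient_id") |>
    dplyr::relocate("patient_id", "selfreport_scale", "asof_day")
  mask_two_level(out)
}
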
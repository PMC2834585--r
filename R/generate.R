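#' Generate a seeded synthetic ART cohort
#'
#' Simulates routine clinic event logs (intake records, visits, pharmacy
#' dispensings, CD4 tests) with the statistical structure the adherence
#' analysis assumes. A single latent adherence propensity per patient jointly
#' drives refill lateness, skipped appointments, and long treatment
#' interruptions, so dispensing-, self-report-, and attendance-based measures
#' are positively correlated. Weight follows a rising concave trajectory
#' (fast early gain, plateau by month nine) with configured penalties for low
#' medicine coverage and treatment gaps; one follow-up CD4 test is drawn in
#' the configured window with gain depending on the coverage band at the test
#' date.
#'
#' Identical `(config, seed)` pairs yield identical cohorts. Under the default
#' configuration every generated patient satisfies the eligibility screen:
#' lateness within the first two quarters is capped and long interruptions
#' start no earlier than the fifth scheduled visit, emulating a cohort whose
#' early dropouts have already been screened out by the inclusion criteria.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with components `cohort` (a [cohort_data()]) and `trace`
#'   (a tibble of per-patient generation truth: latent propensity, true
#'   coverage percent and true >30-day-gap indicator at the index visit),
#'   for parameter-recovery testing.
#' @examples
#' g <- generate_cohort(cohort_config(n_patients = 25), seed = 7)
#' g$cohort
#' @export
generate_cohort <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  set.seed(seed)

  n <- config$n_patients
  dm <- config$demographic_marginals
  am <- config$adherence_model
  om <- config$outcome_model
  interval <- config$schedule_interval_days
  followup_days <- config$followup_months * 30L
  K <- followup_days %/% interval # scheduled follow-up visits after day 0

  id <- sprintf("P%05d", seq_len(n))
  pick <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  bern <- function(p) runif(n) < p

  ## ---- intake record ----
  gender <- pick(dm$gender)
  age_band <- pick(dm$age_band)
  age_years <- integer(n)
  age_years[age_band == "<=30"] <- sample(18:30, sum(age_band == "<=30"), TRUE)
  age_years[age_band == "31-40"] <- sample(31:40, sum(age_band == "31-40"), TRUE)
  age_years[age_band == ">40"] <- sample(41:65, sum(age_band == ">40"), TRUE)
  married <- bern(dm$married)
  education <- pick(dm$education)
  occupation <- pick(dm$occupation)
  living <- pick(dm$living)
  support_partner <- bern(dm$support_partner)
  facility_id <- sample.int(16L, n, TRUE)
  n_two <- round(16 * dm$two_level_scale)
  selfreport_scale <- ifelse(facility_id <= n_two, "two_level", "three_level")
  facility_management <- pick(dm$facility_management)
  location <- pick(dm$location)
  who_stage <- as.integer(pick(dm$who_stage))
  tb_at_initiation <- bern(dm$tb_at_initiation)
  pmtct_history <- bern(dm$pmtct_female) & gender == "female"
  prior_art_exposure <- bern(dm$prior_art_exposure)
  no_schedule <- bern(dm$no_schedule_logged)

  initiation_date <- as.Date("2007-01-01") + (sample.int(365L, n, TRUE) - 1L)
  data_collection_date <- initiation_date + followup_days

  bw <- config$baseline_weight
  baseline_weight <- round(ifelse(
    gender == "male",
    rnorm(n, bw$male[["mean"]], bw$male[["sd"]]),
    rnorm(n, bw$female[["mean"]], bw$female[["sd"]])
  ), 1)
  baseline_weight <- pmax(baseline_weight, 30)

  cd4_band <- pick(config$baseline_cd4_band_probs)
  baseline_cd4 <- integer(n)
  rng <- list("<=100" = 20:100, "101-200" = 101:200,
              "201-350" = 201:350, ">350" = 351:500)
  for (b in names(rng)) {
    k <- cd4_band == b
    if (any(k)) baseline_cd4[k] <- sample(rng[[b]], sum(k), TRUE)
  }
  baseline_cd4_day <- -sample(7:85, n, TRUE) # within 3 months before initiation

  ## ---- latent behaviour ----
  z <- rnorm(n, 0, am$propensity_sd)
  p_perfect <- plogis(qlogis(am$prob_perfect_refill) + z)
  p_miss <- plogis(qlogis(am$missed_visit_prob) - z)
  p_int <- plogis(qlogis(am$prob_long_interruption) - z)

  interrupted <- bern(p_int)
  # interruptions start at scheduled visit 5+ and early enough to be observed
  int_visit <- sample(5:max(5L, K - 3L), n, TRUE)
  dd <- am$interruption_length_distribution
  int_len <- dd$min_days +
    if (dd$mean_extra_days > 0) rgeom(n, 1 / dd$mean_extra_days) else rep(0L, n)

  rd <- am$refill_delay_distribution

  ## ---- visit process (vectorized over patients, loop over visit slots) ----
  # column 1 is the initiation-day visit (day 0, first dispensing)
  A <- matrix(0L, n, K + 1L)      # actual day
  S <- matrix(0L, n, K + 1L)      # scheduled day
  gapm <- matrix(0L, n, K + 1L)   # uncovered days closed at each visit
  Em <- matrix(0L, n, K + 1L)     # coverage-end day after each visit's dispensing
  pool_end <- rep(interval, n)    # supply runs out at this day
  Em[, 1L] <- pool_end

  for (k in seq_len(K)) {
    sched <- A[, k] + interval
    perfect <- runif(n) < p_perfect
    early <- sample.int(rd$early_max_days + 1L, n, TRUE) - 1L
    late <- 1L + rgeom(n, 1 / rd$late_mean_days)
    delay <- ifelse(perfect, -early, late)
    missed <- runif(n) < p_miss
    delay <- delay + ifelse(missed,
                            rd$missed_extra_min_days +
                              rgeom(n, 1 / rd$missed_extra_mean_days), 0L)
    hit <- interrupted & int_visit == k
    delay[hit] <- delay[hit] + int_len[hit]
    # first two quarters: lateness cap guarantees visit continuity (day <= 85
    # between consecutive visits), emulating an already-included cohort
    capped <- sched <= 182L
    delay[capped] <- pmin(delay[capped], 55L)
    a <- as.integer(sched + delay)
    gapm[, k + 1L] <- pmax(0L, a - pool_end)
    pool_end <- pmax(pool_end, a) + interval # carryover of unfinished supply
    A[, k + 1L] <- a
    S[, k + 1L] <- as.integer(sched)
    Em[, k + 1L] <- pool_end
  }

  keep <- A <= followup_days
  Gm <- row_cumsum(gapm)       # uncovered days before each visit
  Mx <- row_cummax(gapm)       # longest closed gap to date
  covpct <- 100 * (A - Gm) / pmax(A, 1L)
  covpct[, 1L] <- 100
  gapflag <- Mx > 30L

  ## ---- visit-level observations ----
  lapse <- gapm > 0L
  u_opt <- matrix(runif(n * (K + 1L)), n)
  u_sev <- matrix(runif(n * (K + 1L)), n)
  code3 <- ifelse(lapse,
                  ifelse(u_opt < am$selfreport_optimism, 1L,
                         ifelse(u_sev < 0.85, 2L, 3L)),
                  ifelse(u_opt < 0.97, 1L, 2L))
  code2 <- ifelse(lapse & u_opt >= am$selfreport_optimism & u_sev >= 0.85, 3L, 1L)
  code <- ifelse(matrix(selfreport_scale == "three_level", n, K + 1L),
                 code3, code2)
  code[matrix(runif(n * (K + 1L)), n) < am$selfreport_miss_prob] <- NA_integer_
  code[, 1L] <- NA_integer_ # nothing to report at initiation

  side_effect <- matrix(runif(n * (K + 1L)) < om$sideeffect_visit_prob, n)
  side_effect[, 1L] <- FALSE
  switch_reg <- matrix(runif(n * (K + 1L)) < om$regimen_switch_prob, n)
  switch_reg[, 1L] <- FALSE
  reg_num <- row_cumsum(switch_reg * 1L) + 1L
  pi_draw <- matrix(runif(n * (K + 1L)) < om$pi_switch_prob, n) & switch_reg
  on_pi <- row_cummax(pi_draw * 1L) > 0L
  regimen_id <- matrix(paste0("reg", reg_num, ifelse(on_pi, "p", "")), n)

  ## ---- weight outcome ----
  gain <- matrix(cumulative_gain(as.numeric(A), om$monthly_weight_gain_kg,
                                 interval), n)
  pen_w <- weight_band_penalty(covpct, om) + om$weight_penalty_gap_kg * gapflag
  rho <- om$within_patient_rho
  b_i <- rnorm(n, 0, om$residual_sd_weight * sqrt(rho))
  e_it <- matrix(rnorm(n * (K + 1L), 0, om$residual_sd_weight * sqrt(1 - rho)), n)
  weight <- baseline_weight + gain + pen_w + b_i + e_it
  weight[, 1L] <- baseline_weight
  weight <- round(weight, 1)
  weight[matrix(runif(n * (K + 1L)), n) < am$weight_missing_prob & col(weight) > 1L] <- NA_real_

  ## ---- follow-up CD4 test ----
  w <- om$cd4_test_window_days
  fu_day <- sample(seq(w[1], min(w[2], followup_days)), n, TRUE)
  # coverage state entering the test day, from the same dispensing history
  kpos <- rowSums(A < fu_day & keep)               # dispensings strictly before test
  idx <- cbind(seq_len(n), kpos)
  open_gap <- pmax(0L, fu_day - Em[idx])
  cov_fu <- 100 * (fu_day - (Gm[idx] + open_gap)) / fu_day
  gap_fu <- pmax(Mx[idx], open_gap) > 30L
  cd4_change <- om$cd4_gain_full_coverage +
    cd4_band_penalty(cov_fu, om) + om$cd4_penalty_gap * gap_fu +
    rnorm(n, 0, om$residual_sd_cd4)
  fu_count <- pmax(0L, as.integer(round(baseline_cd4 + cd4_change)))

  ## ---- assemble tibbles ----
  patients <- tibble::tibble(
    patient_id = id, gender = gender, age_years = age_years,
    age_band = age_band, married = married, education = education,
    occupation = occupation, living = living,
    support_partner = support_partner, facility_id = facility_id,
    facility_management = facility_management, location = location,
    who_stage = who_stage, tb_at_initiation = tb_at_initiation,
    pmtct_history = pmtct_history, prior_art_exposure = prior_art_exposure,
    initiation_date = initiation_date, baseline_weight_kg = baseline_weight,
    baseline_cd4 = baseline_cd4,
    baseline_cd4_date = initiation_date + baseline_cd4_day,
    data_collection_date = data_collection_date,
    selfreport_scale = selfreport_scale
  )

  ord <- which(t(keep)) # row-major: patient blocks in visit order
  pi_idx <- rep(seq_len(n), each = K + 1L)[ord]
  vi_idx <- rep(seq_len(K + 1L), times = n)[ord]
  cell <- cbind(pi_idx, vi_idx)
  visits <- tibble::tibble(
    patient_id = id[pi_idx],
    actual_date = initiation_date[pi_idx] + A[cell],
    scheduled_date = dplyr::if_else(no_schedule[pi_idx], as.Date(NA),
                                    initiation_date[pi_idx] + S[cell]),
    weight_kg = weight[cell],
    selfreport_code = code[cell],
    regimen_id = regimen_id[cell],
    side_effect_or_oi_flag = side_effect[cell]
  )

  drugs <- paste0("d", 1:3)
  m <- nrow(visits)
  dispensings <- tibble::tibble(
    patient_id = rep(visits$patient_id, each = 3L),
    dispense_date = rep(visits$actual_date, each = 3L),
    drug_code = rep(drugs, times = m),
    days_of_supply = rep(interval, 3L * m),
    regimen_id = rep(visits$regimen_id, each = 3L),
    contains_pi = rep(grepl("p$", visits$regimen_id), each = 3L)
  )

  cd4_tests <- tibble::tibble(
    patient_id = c(id, id),
    test_date = c(initiation_date + baseline_cd4_day, initiation_date + fu_day),
    count = c(baseline_cd4, fu_count)
  ) |> dplyr::arrange(.data$patient_id, .data$test_date)

  cohort <- cohort_data(patients, visits, dispensings, cd4_tests)

  # truth at the index visit (visit nearest day 180, ties to earlier)
  day_list <- split(A[cell], pi_idx)
  index_day <- vapply(day_list, function(d) nearest_day(d[d > 0], 180), numeric(1))
  # map back to the visit-slot column of each patient's index visit
  slot <- vapply(seq_len(n), function(i) {
    which(A[i, ] == index_day[i] & keep[i, ])[1]
  }, integer(1))
  tidx <- cbind(seq_len(n), slot)
  trace <- tibble::tibble(
    patient_id = id,
    propensity = z,
    index_day = as.integer(index_day),
    true_coverage_pct = covpct[tidx],
    true_gap_gt30 = gapflag[tidx],
    interrupted = interrupted
  )

  list(cohort = cohort, trace = trace)
}

# cumulative weight gain (kg) at day t under full adherence: piecewise-linear
# interpolation of the monthly increments
cumulative_gain <- function(t, monthly, interval = 30L) {
  nm <- length(monthly)
  frac <- outer(t, interval * (seq_len(nm) - 1L), function(d, s) {
    pmin(1, pmax(0, (d - s) / interval))
  })
  as.numeric(frac %*% monthly)
}

weight_band_penalty <- function(covpct, om) {
  mid <- om$weight_penalty_mid_coverage_kg
  out <- matrix(0, nrow(covpct), ncol(covpct))
  out[covpct < 80] <- om$weight_penalty_low_coverage_kg
  out[covpct >= 80 & covpct < 90] <- mid[["80-90"]]
  out[covpct >= 90 & covpct < 100] <- mid[["90-100"]]
  out
}

cd4_band_penalty <- function(cov, om) {
  mid <- om$cd4_penalty_mid_coverage
  out <- numeric(length(cov))
  out[cov < 80] <- om$cd4_penalty_low_coverage
  out[cov >= 80 & cov < 90] <- mid[["80-90"]]
  out[cov >= 90 & cov < 100] <- mid[["90-100"]]
  out
}
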
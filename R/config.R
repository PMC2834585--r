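#' Configuration for the synthetic ART cohort generator
#'
#' Builds the full parameterization of [generate_cohort()]: demographic
#' marginals, the behavioural adherence model, the visit/dispensing schedule,
#' and the outcome (weight and CD4) model. Defaults emulate a routine-care
#' East African ART cohort: roughly five of eight patients keep uninterrupted
#' medicine coverage through month six, long (>30-day) treatment interruptions
#' are rare, and self-reports are optimistic relative to dispensing records.
#'
#' @details
#' Probability vectors must sum to 1 (within 1e-9). Binary fields are given as
#' a single probability of the first-named level. `adherence_model` is the
#' behavioural core: a single latent per-patient adherence propensity (standard
#' normal scale, SD `propensity_sd`) jointly drives refill lateness, missed
#' visits, and long interruptions, so that dispensing-, self-report-, and
#' attendance-based measures are positively inter-correlated.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Default seed used by [generate_cohort()] when none is passed.
#' @param demographic_marginals Named list of category probabilities; see
#'   [default_config()] for the full set of fields.
#' @param baseline_weight Gender-specific mean/SD of baseline weight in kg.
#' @param baseline_cd4_band_probs Probabilities of the four baseline CD4 bands
#'   (<=100, 101-200, 201-350, >350 cells/mm3).
#' @param adherence_model List of behavioural parameters (see Details).
#' @param schedule_interval_days Scheduled days between clinic visits; each
#'   attended visit dispenses this many days of supply.
#' @param followup_months Months of follow-up captured per patient.
#' @param outcome_model List of outcome-generation parameters: the monthly
#'   weight-gain curve (kg per 30-day month, cumulative under full adherence),
#'   weight/CD4 penalties attached to low-coverage bands and >30-day gaps,
#'   residual SDs, the within-patient correlation of repeated weights, and the
#'   follow-up CD4 test window in days since initiation.
#'
#' @return A `cohort_config` object (a validated named list).
#' @seealso [default_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 488L,
                          seed = 1L,
                          demographic_marginals = default_marginals(),
                          baseline_weight = list(
                            male = c(mean = 57.2, sd = 9.2),
                            female = c(mean = 52.9, sd = 9.7)
                          ),
                          baseline_cd4_band_probs = default_cd4_bands(),
                          adherence_model = default_adherence_model(),
                          schedule_interval_days = 30L,
                          followup_months = 18L,
                          outcome_model = default_outcome_model()) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      seed = as.integer(seed),
      demographic_marginals = demographic_marginals,
      baseline_weight = baseline_weight,
      baseline_cd4_band_probs = baseline_cd4_band_probs,
      adherence_model = adherence_model,
      schedule_interval_days = as.integer(schedule_interval_days),
      followup_months = as.integer(followup_months),
      outcome_model = outcome_model
    ),
    class = "cohort_config"
  )
  validate_config(cfg)
  cfg
}

# Demographic marginals. Categorical cells are the cohort-characteristics
# table of the validation study they emulate, renormalized where the printed
# percentages do not sum to exactly 100 (living 100.1, occupation 99.9).
default_marginals <- function() {
  norm1 <- function(x) x / sum(x)
  list(
    gender = c(female = 0.625, male = 0.375),
    age_band = c("<=30" = 0.293, "31-40" = 0.434, ">40" = 0.273),
    education = c(none = 0.155, primary = 0.467, "secondary+" = 0.378),
    married = 0.441,
    living = norm1(c(alone = 0.060, with_child_only = 0.245, with_adult = 0.696)),
    occupation = norm1(c(employed = 0.283, self_employed = 0.322, unemployed = 0.394)),
    facility_management = c(government = 0.635, other = 0.365),
    location = c(capital = 0.498, other_urban = 0.264, rural = 0.238),
    who_stage = c("1" = 0.089, "2" = 0.254, "3" = 0.544, "4" = 0.113),
    support_partner = 0.887,
    pmtct_female = 0.062,
    tb_at_initiation = 0.152,
    prior_art_exposure = 0,
    two_level_scale = 0.25,   # fraction of facilities recording 2-level self-reports
    no_schedule_logged = 0.06 # fraction of patients whose clinic logs no scheduled dates
  )
}

default_cd4_bands <- function() {
  x <- c("<=100" = 0.374, "101-200" = 0.404, "201-350" = 0.209, ">350" = 0.016)
  x / sum(x)
}

default_adherence_model <- function() {
  list(
    propensity_sd = 1,
    prob_perfect_refill = 0.93,
    refill_delay_distribution = list(
      early_max_days = 3,          # on-time refills arrive 0-3 days early
      late_mean_days = 4,          # ordinary lateness: 1 + geometric, mean ~4
      missed_extra_min_days = 10,  # a skipped appointment adds 10+ days
      missed_extra_mean_days = 10
    ),
    prob_long_interruption = 0.027,
    interruption_length_distribution = list(min_days = 31, mean_extra_days = 15),
    missed_visit_prob = 0.04,
    selfreport_optimism = 0.8,   # P(report "perfect" despite a true lapse)
    selfreport_miss_prob = 0.10, # visit without a recorded self-report
    weight_missing_prob = 0.03
  )
}

default_outcome_model <- function() {
  list(
    # cumulative gain 3.9 kg by month 6 under full adherence, plateau by month 9
    monthly_weight_gain_kg = c(1.3, 0.9, 0.6, 0.45, 0.35, 0.3, 0.25, 0.2, 0.15,
                               rep(0, 9)),
    weight_penalty_low_coverage_kg = -2.24,
    weight_penalty_mid_coverage_kg = c("80-90" = -0.51, "90-100" = -0.52),
    weight_penalty_gap_kg = -3.26,
    cd4_gain_full_coverage = 148.8,
    cd4_penalty_low_coverage = -97.3,
    cd4_penalty_mid_coverage = c("80-90" = -28.8, "90-100" = -22.1),
    cd4_penalty_gap = 0,
    residual_sd_weight = 4.5,
    within_patient_rho = 0.5,
    residual_sd_cd4 = 120,
    cd4_test_window_days = c(91L, 270L),
    sideeffect_visit_prob = 0.05,
    regimen_switch_prob = 0.03,
    pi_switch_prob = 0.2
  )
}

#' Default synthetic cohort configuration
#'
#' Returns the fully populated default [cohort_config()]. Pure: two calls
#' return identical configurations.
#'
#' @return A `cohort_config` object.
#' @examples
#' cfg <- default_config()
#' cfg$demographic_marginals$gender[["female"]]
#' @export
default_config <- function() cohort_config()

# hard-validates a cohort_config; called before any generation
validate_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) abort("`config` must be a `cohort_config`")
  assert_scalar_count(cfg$n_patients, "n_patients")
  assert_scalar_count(cfg$schedule_interval_days, "schedule_interval_days")
  assert_scalar_count(cfg$followup_months, "followup_months")
  check_probs <- function(x, name) {
    if (length(x) > 1L) {
      if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
        abort(sprintf("probabilities in `%s` must be >= 0 and sum to 1", name))
      }
    } else if (is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1]", name))
    }
  }
  for (nm in names(cfg$demographic_marginals)) {
    check_probs(cfg$demographic_marginals[[nm]], nm)
  }
  check_probs(cfg$baseline_cd4_band_probs, "baseline_cd4_band_probs")
  am <- cfg$adherence_model
  if (am$propensity_sd <= 0) abort("`propensity_sd` must be > 0")
  for (nm in c("prob_perfect_refill", "prob_long_interruption",
               "missed_visit_prob", "selfreport_optimism",
               "selfreport_miss_prob", "weight_missing_prob")) {
    check_probs(am[[nm]], nm)
  }
  if (am$interruption_length_distribution$min_days < 1) {
    abort("interruption `min_days` must be >= 1")
  }
  om <- cfg$outcome_model
  if (om$residual_sd_weight <= 0 || om$residual_sd_cd4 <= 0) {
    abort("residual SDs must be > 0")
  }
  if (om$within_patient_rho < 0 || om$within_patient_rho >= 1) {
    abort("`within_patient_rho` must be in [0, 1)")
  }
  eff <- unlist(om[c("weight_penalty_low_coverage_kg", "weight_penalty_mid_coverage_kg",
                     "weight_penalty_gap_kg", "cd4_gain_full_coverage",
                     "cd4_penalty_low_coverage", "cd4_penalty_mid_coverage",
                     "cd4_penalty_gap", "monthly_weight_gain_kg")])
  if (any(!is.finite(eff))) abort("all outcome effect parameters must be finite")
  w <- om$cd4_test_window_days
  if (length(w) != 2L || w[1] < 1 || w[2] <= w[1]) {
    abort("`cd4_test_window_days` must be an increasing pair of positive days")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  schedule: every", x$schedule_interval_days, "days for",
      x$followup_months, "months\n")
  cat("  adherence: P(perfect refill) =", x$adherence_model$prob_perfect_refill,
      ", P(long interruption) =", x$adherence_model$prob_long_interruption, "\n")
  invisible(x)
}
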
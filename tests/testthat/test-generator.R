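test_that("identical (config, seed) reproduces the cohort exactly", {
  cfg <- cohort_config(n_patients = 30)
  a <- generate_cohort(cfg, seed = 77)
  b <- generate_cohort(cfg, seed = 77)
  expect_identical(a$cohort$patients, b$cohort$patients)
  expect_identical(a$cohort$visits, b$cohort$visits)
  expect_identical(a$cohort$dispensings, b$cohort$dispensings)
  expect_identical(a$cohort$cd4_tests, b$cohort$cd4_tests)
  expect_identical(a$trace, b$trace)
  c <- generate_cohort(cfg, seed = 78)
  expect_false(identical(a$cohort$visits, c$cohort$visits))
})

test_that("default configuration is pure and validates", {
  expect_identical(default_config(), default_config())
  expect_silent(adherr:::validate_config(default_config()))
  expect_equal(default_config()$demographic_marginals$gender[["female"]],
               0.625)
})

test_that("config invariants are enforced before any generation", {
  cfg <- default_config()
  cfg$demographic_marginals$location <- c(capital = 0.6, other_urban = 0.3,
                                          rural = 0.2)
  expect_error(generate_cohort(cfg, seed = 1), "sum to 1")
  cfg2 <- default_config()
  cfg2$outcome_model$residual_sd_weight <- 0
  expect_error(generate_cohort(cfg2, seed = 1), "SD")
})

test_that("perfectly adherent configuration yields full coverage and no gaps", {
  cfg <- cohort_config(n_patients = 40)
  cfg$adherence_model$prob_perfect_refill <- 1
  cfg$adherence_model$missed_visit_prob <- 0
  cfg$adherence_model$prob_long_interruption <- 0
  g <- generate_cohort(cfg, seed = 4)
  s <- cohort_snapshots(g$cohort, at = "index")
  expect_true(all(s$pct_days_covered == 100))
  expect_true(all(!s$gap_gt30))
})

test_that("forced 40-day interruptions flag every patient", {
  cfg <- cohort_config(n_patients = 40)
  cfg$adherence_model$prob_perfect_refill <- 1
  cfg$adherence_model$missed_visit_prob <- 0
  cfg$adherence_model$prob_long_interruption <- 1
  cfg$adherence_model$propensity_sd <- 1e-9
  cfg$adherence_model$refill_delay_distribution$early_max_days <- 0
  cfg$adherence_model$interruption_length_distribution <-
    list(min_days = 40, mean_extra_days = 0)
  g <- generate_cohort(cfg, seed = 4)
  s <- cohort_snapshots(g$cohort, at = "visits")
  last <- s |> dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$asof_day, n = 1) |> dplyr::ungroup()
  expect_true(all(last$gap_gt30))
})

test_that("categorical marginals are reproduced within 3 binomial SEs", {
  g <- generate_cohort(cohort_config(n_patients = 2000), seed = 31)
  p <- g$cohort$patients
  dm <- default_config()$demographic_marginals
  check <- function(obs_frac, prob, n) {
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(obs_frac - prob), 3 * se + 1e-12)
  }
  n <- nrow(p)
  check(mean(p$gender == "female"), dm$gender[["female"]], n)
  check(mean(p$married), dm$married, n)
  for (lv in names(dm$location)) {
    check(mean(p$location == lv), dm$location[[lv]], n)
  }
  for (lv in names(dm$who_stage)) {
    check(mean(p$who_stage == as.integer(lv)), dm$who_stage[[lv]], n)
  }
})

test_that("every default-config patient passes the eligibility screen", {
  g <- generate_cohort(cohort_config(n_patients = 500), seed = 15)
  rep <- screen_eligibility(g$cohort)
  expect_equal(nrow(rep$excluded), 0L)
})

test_that("generation trace agrees with the indicator engine at the index visit", {
  g <- generate_cohort(cohort_config(n_patients = 120), seed = 8)
  s <- cohort_snapshots(g$cohort, at = "index")
  tr <- g$trace[match(s$patient_id, g$trace$patient_id), ]
  expect_equal(s$asof_day, tr$index_day)
  expect_equal(s$pct_days_covered, tr$true_coverage_pct)
  expect_equal(s$gap_gt30, tr$true_gap_gt30)
})

test_that("weights rise fast early and plateau, anchored near 3.9 kg at month 6", {
  cfg <- cohort_config(n_patients = 600)
  cfg$adherence_model$prob_perfect_refill <- 1
  cfg$adherence_model$missed_visit_prob <- 0
  cfg$adherence_model$prob_long_interruption <- 0
  g <- generate_cohort(cfg, seed = 2)
  init <- setNames(g$cohort$patients$initiation_date,
                   g$cohort$patients$patient_id)
  bw <- setNames(g$cohort$patients$baseline_weight_kg,
                 g$cohort$patients$patient_id)
  v <- g$cohort$visits |>
    dplyr::mutate(day = as.integer(.data$actual_date - init[.data$patient_id]),
                  gain = .data$weight_kg - bw[.data$patient_id])
  m6 <- mean(v$gain[abs(v$day - 180) <= 15], na.rm = TRUE)
  m3 <- mean(v$gain[abs(v$day - 90) <= 15], na.rm = TRUE)
  m12 <- mean(v$gain[abs(v$day - 360) <= 15], na.rm = TRUE)
  expect_equal(m6, 3.9, tolerance = 0.15)
  expect_gt(m3, 0.6 * m6)           # concave: most gain happens early
  expect_lt(m12 - m6, 0.31 * m6)    # plateau after month nine
})
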
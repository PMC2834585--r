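test_that("the weight panel keeps in-window visits with recorded weights", {
  p <- fixture_patient()
  v <- fixture_visits("P1", c(0, 30, 60, 90, 280))
  v$weight_kg[3] <- NA # visit without a weight drops out
  co <- cohort_data(p, v, fixture_dispensings("P1", c(0, 30, 60, 90, 280)),
                    fixture_cd4("P1", c(-30, 180), c(150, 280)))
  panel <- build_weight_panel(co)
  expect_equal(panel$asof_day, c(30, 90)) # day 0 is baseline, 280 beyond 270
  ex <- attr(panel, "exclusions")
  expect_equal(ex$visits_missing_weight, 1L)
  expect_true(all(c("month", "n_regimens", "ever_pi", "who34") %in%
                    names(panel)))
})

test_that("the CD4 table picks the window test nearest day 180, ties earlier", {
  mk <- function(days, counts = rep(300, length(days))) {
    co <- cohort_data(fixture_patient(),
                      fixture_visits("P1", c(0, 30, 60, 90, 120)),
                      fixture_dispensings("P1", c(0, 30, 60, 90, 120)),
                      fixture_cd4("P1", c(-30, days), c(150, counts)))
    build_cd4_table(co)
  }
  expect_equal(mk(c(100, 250))$days_to_test, 250) # |250-180| < |100-180|
  expect_equal(mk(c(110, 250))$days_to_test, 110) # equidistant: earlier wins
  expect_equal(mk(180)$days_to_test, 180)
  expect_equal(nrow(mk(300)), 0L) # outside the window: patient excluded
  expect_equal(mk(180, 280)$cd4_change, 130)
})

test_that("models refuse an indicator with a single observed level", {
  g <- generate_cohort(cohort_config(n_patients = 60), seed = 3)
  cd4 <- build_cd4_table(g$cohort)
  cd4$pct_days_covered <- 100 # force one band
  expect_error(fit_cd4_model(cd4, "coverage_band"), "single level")
})

test_that("self-report models exclude 2-level-scale patients and count them", {
  g <- generate_cohort(cohort_config(n_patients = 250), seed = 6)
  cd4 <- build_cd4_table(g$cohort)
  m <- fit_cd4_model(cd4, "any_imperfect")
  n_two <- sum(cd4$selfreport_scale == "two_level")
  expect_gt(n_two, 0)
  expect_lte(m$n_patients, nrow(cd4) - n_two)
  expect_equal(m$n_patients + m$n_patients_excluded, nrow(cd4))
})

test_that("weight model recovers a known gap penalty on one large cohort", {
  cfg <- cohort_config(n_patients = 2000)
  cfg$outcome_model$weight_penalty_low_coverage_kg <- 0
  cfg$outcome_model$weight_penalty_mid_coverage_kg[] <- 0
  cfg$outcome_model$weight_penalty_gap_kg <- -3
  g <- generate_cohort(cfg, seed = 12)
  panel <- build_weight_panel(g$cohort)
  m <- fit_weight_model(panel, "gap_gt30")
  est <- m$indicator_terms
  expect_equal(est$term, "gap_gt30TRUE")
  expect_lt(abs(est$estimate - (-3)), 0.8)
  expect_true(est$conf.low < -3 + 1 & est$conf.high > -3 - 1)
})

test_that("adjusted predictions are linear-model consistent", {
  g <- generate_cohort(cohort_config(n_patients = 300), seed = 14)
  cd4 <- build_cd4_table(g$cohort)
  m <- fit_cd4_model(cd4, "gap_gt30")
  # population mode equals the mean of per-row predictions
  pr <- adjusted_prediction(m, mode = "population")
  mf <- model.frame(m$fit)
  nd <- mf
  nd$gap_gt30 <- TRUE
  by_hand <- mean(predict(m$fit, newdata = nd))
  expect_equal(pr$estimate[pr$level == "TRUE"], by_hand, tolerance = 1e-10)

  # typical mode: gender flips only gender-linked terms, and a missing
  # covariate is named
  prof <- list(gender = "female", age_band = "31-40", married = TRUE,
               location = "capital", baseline_cd4 = 139.8,
               who34 = FALSE, tb_at_initiation = FALSE,
               side_effect_to_date = FALSE, n_regimens = 1L,
               ever_pi = FALSE, days_to_test = 180)
  pf <- adjusted_prediction(m, profile = prof, mode = "typical")
  prof_m <- prof
  prof_m$gender <- "male"
  pm <- adjusted_prediction(m, profile = prof_m, mode = "typical")
  gender_coef <- coef(m$fit)[["gendermale"]]
  expect_equal(pm$estimate - pf$estimate, rep(gender_coef, nrow(pf)),
               tolerance = 1e-10)
  expect_error(adjusted_prediction(m, profile = prof[-3], mode = "typical"),
               "married")
})

test_that("intercept-only structure predicts the intercept everywhere", {
  d <- data.frame(y = rnorm(40), g = rep(c(0, 1), 20),
                  id = rep(1:20, each = 2))
  fit <- gee_gauss(y ~ g, d, id = id, corstr = "independence")
  fake <- structure(list(kind = "gee_weight", indicator = "g",
                         indicator_var = "g", fit = fit),
                    class = "adherence_model")
  fit$coefficients[["g"]] <- 0
  fake$fit <- fit
  pr <- adjusted_prediction(fake, mode = "population")
  expect_equal(pr$estimate, rep(fit$coefficients[["(Intercept)"]], 2),
               tolerance = 1e-12)
})
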
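test_that("pearson cells behave at the identities and degeneracies", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  z <- pearson_r(rep(2, 5), x)
  expect_true(is.na(z$estimate))
  expect_match(z$note, "zero variance")
  expect_equal(pearson_r(c(1, NA, 3, 4), c(2, 5, NA, 8))$n, 2L)
})

test_that("kendall tau-b hits the perfect-concordance corners", {
  expect_equal(kendall_tau(c(0, 0, 1, 1), c(0, 0, 1, 1))$estimate, 1)
  expect_equal(kendall_tau(c(0, 1, 0, 1), c(1, 0, 1, 0))$estimate, -1)
  z <- kendall_tau(c(1, 1, 1, 1), c(0, 1, 0, 1))
  expect_true(is.na(z$estimate))
  expect_match(z$note, "tied")
})

test_that("tau-b equals exhaustive pair counting on random tied data", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    x <- switch(sample(3, 1),
                rnorm(n), sample(0:1, n, TRUE), sample(1:4, n, TRUE))
    y <- switch(sample(3, 1),
                rnorm(n), sample(0:1, n, TRUE), sample(1:4, n, TRUE))
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau(x, y)$estimate, brute_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-value is available for tiny samples", {
  x <- c(1, 0, 1, 0, 1)
  y <- c(2, 1, 3, 1, 2)
  z <- kendall_tau(x, y, exact = TRUE)
  expect_true(z$p_value >= 0 && z$p_value <= 1)
  # enumeration over all 5! permutations, so repeated calls are identical
  expect_equal(z$p_value, kendall_tau(x, y, exact = TRUE)$p_value)
  expect_error(kendall_tau(rnorm(10), rnorm(10), exact = TRUE), "n <= 7")
})

test_that("the matrix picks the method by measure kind and varies n by pair", {
  g <- generate_cohort(cohort_config(n_patients = 300), seed = 19)
  s <- cohort_snapshots(g$cohort, at = "index")
  cm <- correlation_matrix(s)
  get <- function(a, b) cm[cm$measure1 == a & cm$measure2 == b, ]
  expect_equal(get("pct_days_covered", "pct_visits_on_or_before")$method,
               "pearson")
  expect_equal(get("pct_days_covered", "gap_gt30")$method, "kendall")
  expect_equal(get("coverage_gt80", "coverage_gt95")$method, "kendall")
  # self-report pairs lose the 2-level-scale patients
  n_three <- sum(s$selfreport_scale == "three_level" & !is.na(s$avg_selfreport))
  expect_equal(get("pct_days_covered", "avg_selfreport")$n, n_three)
  expect_equal(get("pct_days_covered", "pct_visits_before_exhaustion")$n,
               nrow(s))
  # timeliness pairs lose patients with no recorded scheduled dates
  expect_lt(get("pct_days_covered", "pct_visits_on_or_before")$n, nrow(s))
  # a measure against itself is a unit correlation
  expect_equal(pearson_r(s$pct_days_covered, s$pct_days_covered)$estimate, 1)
})

test_that("the latent-propensity generator reproduces the expected sign pattern", {
  g <- generate_cohort(cohort_config(n_patients = 2000), seed = 23)
  s <- cohort_snapshots(g$cohort, at = "index")
  cm <- correlation_matrix(s)
  get <- function(a, b) cm[cm$measure1 == a & cm$measure2 == b, ]
  expect_gt(get("pct_days_covered", "pct_visits_on_or_before")$estimate, 0)
  expect_gt(get("pct_days_covered", "pct_visits_within_3d")$estimate, 0)
  expect_lt(get("pct_days_covered", "gap_gt30")$estimate, 0)
  expect_lt(get("pct_days_covered", "any_imperfect_selfreport")$estimate, 0)
  expect_gt(get("pct_days_covered", "avg_selfreport")$p_value, 0) # estimable
  expect_lt(get("pct_days_covered", "avg_selfreport")$estimate, 0)
})
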
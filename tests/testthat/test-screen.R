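screen_one <- function(patient, visits, dispensings, cd4) {
  co <- cohort_data(patient, visits, dispensings, cd4)
  screen_eligibility(co)
}

test_that("minors are excluded with reason age", {
  rep <- screen_one(fixture_patient(age_years = 17),
                    fixture_visits("P1", c(20, 110)),
                    fixture_dispensings("P1", c(20, 110)),
                    fixture_cd4("P1", -60, 150))
  expect_equal(rep$excluded$reason, "age")
  expect_length(rep$included, 0L)
})

test_that("a patient meeting all criteria is included", {
  rep <- screen_one(fixture_patient(),
                    fixture_visits("P1", c(20, 110)),
                    fixture_dispensings("P1", c(20, 110)),
                    fixture_cd4("P1", c(-60, 120), c(150, 250)))
  expect_equal(rep$included, "P1")
  expect_equal(nrow(rep$excluded), 0L)
})

test_that("a baseline CD4 older than 3 months fails cd4_availability", {
  rep <- screen_one(fixture_patient(),
                    fixture_visits("P1", c(20, 110)),
                    fixture_dispensings("P1", c(20, 110)),
                    fixture_cd4("P1", c(-120, 120), c(150, 250)))
  expect_equal(rep$excluded$reason, "cd4_availability")
})

test_that("visit continuity needs a visit in each of the first two quarters", {
  # both visits inside quarter 1
  rep <- screen_one(fixture_patient(),
                    fixture_visits("P1", c(20, 80)),
                    fixture_dispensings("P1", c(20, 80)),
                    fixture_cd4("P1", c(-60, 120), c(150, 250)))
  expect_equal(rep$excluded$reason, "visit_continuity")
})

test_that("exclusion goes to the first failed criterion and fractions count all", {
  p <- dplyr::bind_rows(
    fixture_patient("A", age_years = 17),       # fails age AND cd4 below
    fixture_patient("B")                        # fails cd4 only
  )
  v <- dplyr::bind_rows(fixture_visits("A", c(20, 110)),
                        fixture_visits("B", c(20, 110)))
  d <- dplyr::bind_rows(fixture_dispensings("A", 20),
                        fixture_dispensings("B", 20))
  cd <- fixture_cd4("A", -200, 100) # A: stale baseline; B: none at all
  rep <- screen_eligibility(cohort_data(p, v, d, cd))
  reasons <- setNames(rep$excluded$reason, rep$excluded$patient_id)
  expect_equal(reasons[["A"]], "age")
  expect_equal(reasons[["B"]], "cd4_availability")
  fr <- setNames(rep$fractions$n_failed, rep$fractions$criterion)
  expect_equal(fr[["age"]], 1)
  expect_equal(fr[["cd4_availability"]], 2) # A counted here too
  # first-failure attribution: per-criterion fractions sum >= overall
  expect_gte(sum(rep$fractions$fraction), nrow(rep$excluded) / rep$n_screened)
})

test_that("screening is independent of input row order", {
  g <- generate_cohort(cohort_config(n_patients = 40), seed = 9)
  co <- g$cohort
  set.seed(1)
  shuffled <- cohort_data(
    co$patients[sample(nrow(co$patients)), ],
    co$visits[sample(nrow(co$visits)), ],
    co$dispensings[sample(nrow(co$dispensings)), ],
    co$cd4_tests[sample(nrow(co$cd4_tests)), ]
  )
  expect_equal(tidy(screen_eligibility(shuffled)),
               tidy(screen_eligibility(co)))
})
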
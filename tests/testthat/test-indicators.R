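test_that("average self-report is the running mean of recorded codes", {
  v <- fixture_visits("P1", c(30, 60, 90), code = c(1L, 1L, 2L))
  expect_equal(avg_selfreport(v, ORIGIN + 90), 4 / 3)
  expect_equal(avg_selfreport(v, ORIGIN + 60), 1)
  expect_true(is.na(avg_selfreport(v, ORIGIN + 10)))
  v$selfreport_code[2] <- 5L
  expect_error(avg_selfreport(v, ORIGIN + 90), "codes")
})

test_that("self-report flags distinguish poor from merely imperfect", {
  f <- function(codes) {
    selfreport_flags(fixture_visits("P1", 30 * seq_along(codes), code = codes),
                     ORIGIN + 400)
  }
  expect_equal(f(c(1L, 2L, 1L)), c(any_poor = FALSE, any_imperfect = TRUE))
  expect_equal(f(c(1L, 1L)), c(any_poor = FALSE, any_imperfect = FALSE))
  expect_equal(f(3L), c(any_poor = TRUE, any_imperfect = TRUE))
})

test_that("appointment keeping handles the boundary days exactly", {
  v <- function(actual) fixture_visits("P1", actual, sched = 30)
  expect_equal(visit_timeliness(v(30), ORIGIN + 60)$pct_on_or_before, 100)
  expect_equal(visit_timeliness(v(30), ORIGIN + 60)$pct_within_3d, 100)
  t33 <- visit_timeliness(v(33), ORIGIN + 60)
  expect_equal(t33$pct_on_or_before, 0)
  expect_equal(t33$pct_within_3d, 100)
  t34 <- visit_timeliness(v(34), ORIGIN + 60)
  expect_equal(t34$pct_on_or_before, 0)
  expect_equal(t34$pct_within_3d, 0)
  # no scheduled dates -> absent, not zero
  none <- visit_timeliness(fixture_visits("P1", 30, sched = NA), ORIGIN + 60)
  expect_true(is.na(none$pct_on_or_before))
})

test_that("exhaustion-timeliness uses the previous visit's supply, no carryover", {
  v <- fixture_visits("P1", c(0, 30))
  d <- fixture_dispensings("P1", c(0, 30))
  expect_equal(pct_visits_before_exhaustion(v, d, ORIGIN + 60), 100)
  # one day late counts against, even with stockpiled supply from an early refill
  v2 <- fixture_visits("P1", c(0, 20, 51))
  d2 <- fixture_dispensings("P1", c(0, 20))
  x <- build_coverage_timeline(d2, ORIGIN, ORIGIN + 52)
  expect_equal(pct_days_covered(x), 100) # the patient never actually ran out
  expect_equal(pct_visits_before_exhaustion(v2, d2, ORIGIN + 60), 50)
  # visits day 28 and 56 with supplies on 0 and 28 are both timely
  v3 <- fixture_visits("P1", c(0, 28, 56))
  d3 <- fixture_dispensings("P1", c(0, 28))
  expect_equal(pct_visits_before_exhaustion(v3, d3, ORIGIN + 60), 100)
  # previous visit without a dispensing drops that pair from the denominator
  v4 <- fixture_visits("P1", c(0, 30, 65))
  d4 <- fixture_dispensings("P1", c(0, 30))
  expect_equal(pct_visits_before_exhaustion(v4, d4, ORIGIN + 90), 50)
  d5 <- fixture_dispensings("P1", 30)
  expect_equal(pct_visits_before_exhaustion(v4, d5, ORIGIN + 90), 0)
})

test_that("the index visit is the one nearest day 180, ties to the earlier", {
  f <- function(days) {
    as.integer(select_index_visit(fixture_visits("P1", days), ORIGIN) - ORIGIN)
  }
  expect_equal(f(c(150, 200)), 200)
  expect_equal(f(c(160, 200)), 160)
  expect_equal(f(90), 90)
})

test_that("coverage bands are half-open with an exact-100 reference", {
  expect_equal(as.character(categorize_coverage(95, "table2")), "95% to <100%")
  expect_equal(as.character(categorize_coverage(100, "model")), "100%")
  expect_equal(as.character(categorize_coverage(79.999, "model")), "<80%")
  expect_equal(as.character(categorize_coverage(99.999, "table2")),
               "95% to <100%")
  expect_equal(as.character(categorize_coverage(80, "model")), "80% to <90%")
  expect_error(categorize_coverage(101, "model"), "0, 100")
})

test_that("a fully adherent patient snapshots clean at day 180", {
  co <- fixture_cohort(months = 7)
  s <- snapshot_at(co, "P1", ORIGIN + 180)
  expect_equal(s$pct_days_covered, 100)
  expect_false(s$gap_gt30)
  expect_equal(s$longest_gap_days, 0L)
  expect_equal(s$avg_selfreport, 1)
  expect_false(s$any_imperfect_selfreport)
  expect_equal(s$pct_visits_on_or_before, 100)
  expect_equal(s$pct_visits_before_exhaustion, 100)
})

test_that("2-level-scale patients get absent self-report but present dispensing measures", {
  co <- fixture_cohort(patient = fixture_patient(scale = "two_level"))
  s <- snapshot_at(co, "P1", ORIGIN + 180)
  expect_true(is.na(s$avg_selfreport))
  expect_true(is.na(s$any_imperfect_selfreport))
  expect_equal(s$pct_days_covered, 100)
})

test_that("snapshots outside the observation horizon are refused", {
  co <- fixture_cohort(months = 7)
  expect_error(snapshot_at(co, "P1", ORIGIN + 600), "horizon")
  expect_error(snapshot_at(co, "P1", ORIGIN - 5), "first recorded visit")
})

test_that("snapshot invariants hold across a generated cohort", {
  g <- generate_cohort(cohort_config(n_patients = 150), seed = 21)
  s <- cohort_snapshots(g$cohort, at = "visits")
  expect_true(all(s$pct_visits_within_3d >= s$pct_visits_on_or_before,
                  na.rm = TRUE))
  expect_true(all(s$pct_days_covered[s$gap_gt30] < 100))
  expect_true(all(s$pct_days_covered >= 0 & s$pct_days_covered <= 100))
  # gap flag bounds coverage: >30 uncovered days out of asof_day
  flagged <- s[s$gap_gt30, ]
  expect_true(all(flagged$pct_days_covered <=
                    100 * (flagged$asof_day - 31) / flagged$asof_day + 1e-9))
  perfect <- s[!is.na(s$avg_selfreport) & s$avg_selfreport == 1, ]
  expect_true(all(!perfect$any_poor_selfreport &
                    !perfect$any_imperfect_selfreport))
})

test_that("snapshot_at agrees with the cohort-level vectorized path", {
  g <- generate_cohort(cohort_config(n_patients = 20), seed = 13)
  s <- cohort_snapshots(g$cohort, at = "index")
  for (i in c(1, 7, 20)) {
    pid <- s$patient_id[i]
    init <- g$cohort$patients$initiation_date[
      g$cohort$patients$patient_id == pid]
    one <- snapshot_at(g$cohort, pid, init + s$asof_day[i])
    expect_equal(one$pct_days_covered, s$pct_days_covered[i])
    expect_equal(one$pct_visits_before_exhaustion,
                 s$pct_visits_before_exhaustion[i])
    expect_equal(one$avg_selfreport, s$avg_selfreport[i])
  }
})
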
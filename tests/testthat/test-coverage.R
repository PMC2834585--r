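tl <- function(disp_days, supply = 30L, asof = 90L) {
  build_coverage_timeline(fixture_dispensings("P1", disp_days, supply),
                          ORIGIN, ORIGIN + asof)
}

test_that("seamless refills cover every day", {
  x <- tl(c(0, 30, 60), asof = 90)
  expect_equal(pct_days_covered(x), 100)
  expect_equal(longest_gap(x), 0L)
  expect_false(gap_exceeds(x))
})

test_that("a late refill leaves exactly the uncovered run in between", {
  x <- tl(c(0, 45), asof = 90)
  expect_equal(x$intervals$start_day, c(0, 45))
  expect_equal(x$intervals$end_day, c(30, 75))
  expect_equal(pct_days_covered(x), 100 * 60 / 90)
  expect_equal(longest_gap(x), 15L)
})

test_that("early refills carry unfinished supply over (stockpiling)", {
  x <- tl(c(0, 20), asof = 60)
  expect_equal(x$supply_pool_trace$pool_after, c(30, 40))
  expect_equal(pct_days_covered(x), 100)
})

test_that("percent of days covered follows the defining arithmetic", {
  expect_equal(pct_days_covered(tl(c(0, 45), asof = 90)), 66.6667,
               tolerance = 1e-4)
  expect_equal(pct_days_covered(tl(numeric(0), asof = 90)), 0)
  expect_equal(pct_days_covered(tl(0, supply = 120L, asof = 90)), 100)
})

test_that("the >30-day gap flag is strict", {
  # uncovered days 30..60 inclusive: 31 days
  x <- tl(c(0, 61), asof = 90)
  expect_equal(longest_gap(x), 31L)
  expect_true(gap_exceeds(x))
  # uncovered days 30..59: exactly 30 days -> not flagged
  y <- tl(c(0, 60), asof = 90)
  expect_equal(longest_gap(y), 30L)
  expect_false(gap_exceeds(y))
})

test_that("uncovered days after the last supply count toward the gap", {
  x <- tl(0, asof = 90)
  expect_equal(longest_gap(x), 60L)
  expect_true(gap_exceeds(x))
})

test_that("window and date preconditions are enforced", {
  expect_error(tl(0, asof = 0), "after")
  expect_error(build_coverage_timeline(fixture_dispensings("P1", -5),
                                       ORIGIN, ORIGIN + 90),
               "before initiation")
  x <- tl(c(0, 95), asof = 90) # dispensing beyond the window is noted
  expect_match(x$notes, "ignored")
  expect_equal(max(x$intervals$end_day), 30)
})

test_that("multi-component dispensings cover only while all components last", {
  d <- dplyr::bind_rows(
    fixture_dispensings("P1", 0, supply = 30L),
    dplyr::mutate(fixture_dispensings("P1", 0, supply = 14L), drug_code = "d2")
  )
  x <- build_coverage_timeline(d, ORIGIN, ORIGIN + 30)
  expect_equal(pct_days_covered(x), 100 * 14 / 30, tolerance = 1e-9)
})

test_that("interval engine equals the day-by-day pool oracle on random histories", {
  set.seed(42)
  for (i in 1:300) {
    h <- random_history()
    x <- build_coverage_timeline(
      fixture_dispensings("P1", h$disp_day, 30L) |>
        dplyr::mutate(days_of_supply = h$supply),
      ORIGIN, ORIGIN + h$t
    )
    oracle <- naive_coverage(h$disp_day, h$supply, h$t)
    expect_equal(pct_days_covered(x), oracle$pct)
    expect_equal(longest_gap(x), as.integer(oracle$longest_gap))
  }
})

test_that("adding a dispensing never lowers coverage nor lengthens the gap", {
  set.seed(7)
  for (i in 1:100) {
    h <- random_history()
    base <- tl_from(h$disp_day, h$supply, h$t)
    extra_day <- sample(0:(h$t - 1), 1)
    more <- tl_from(c(h$disp_day, extra_day), c(h$supply, 30L), h$t)
    expect_gte(pct_days_covered(more), pct_days_covered(base))
    expect_lte(longest_gap(more), longest_gap(base))
  }
})
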
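# Time-to-onset summaries, histograms and cumulative curves.

test_that("onset summary quartiles use linear interpolation", {
  r <- make_reports(5, onset = c(0, 0, 1, 2, 33))
  s <- onset_summary(r)
  expect_equal(s$median, 1)
  expect_equal(s$q1, 0)
  expect_equal(s$q3, 2)
  expect_equal(s$n, 5L)
  # heavy tail: mean far above median (hand-computed: 2170/7 = 310)
  r2 <- make_reports(7, onset = c(rep(0, 6), 2170))
  s2 <- onset_summary(r2)
  expect_equal(s2$median, 0)
  expect_equal(s2$mean, 310.0)
  # all missing -> flagged undefined
  s3 <- onset_summary(make_reports(3, onset = NA_real_))
  expect_equal(s3$n, 0L)
  expect_equal(s3$n_missing, 3L)
  expect_true(s3$undefined)
})

test_that("quantile routine agrees with a sort-and-index oracle", {
  # oracle: for p in {.25,.5,.75} on sorted x of length n, the type-7 value
  # is x[h] + (h - floor(h)) * (x[h+1] - x[h]) with h = 1 + p(n-1), computed
  # here by direct indexing
  oracle_q <- function(x, p) {
    x <- sort(x)
    h <- 1 + p * (length(x) - 1)
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(5)
  for (n in 1:12) {
    for (rep in 1:5) {
      x <- sample.int(20, n, replace = TRUE)
      s <- onset_summary(make_reports(n, onset = x))
      expect_equal(s$q1, oracle_q(x, 0.25))
      expect_equal(s$median, oracle_q(x, 0.5))
      expect_equal(s$q3, oracle_q(x, 0.75))
    }
  }
})

test_that("per-term onset summaries restrict to reports listing the term", {
  r <- make_reports(3, onset = c(0, 10, 20))
  sym <- tibble::tibble(report_id = c("s001", "s002"),
                        preferred_term = c("Pyrexia", "Pyrexia"))
  s <- onset_summary(r, sym, "pyrexia ", "serious")  # case/space-insensitive
  expect_equal(s$n, 2L)
  expect_equal(s$median, 5)
  expect_equal(s$stratum, "serious")
})

test_that("histogram bins are closed on both ends at the printed edges", {
  r <- make_reports(6, onset = c(0, 1, 30, 31, 360, 361))
  h <- onset_histogram(r, vaccine_total = 6)
  expect_equal(h$count, c(3L, 1L, 0L, 1L, 1L))
  expect_equal(sum(h$count), 6)
  expect_equal(h$frequency_per_100k[1], 50000L)
  # empty input -> all-zero bins
  h0 <- onset_histogram(make_reports(2, onset = NA_real_), vaccine_total = 2)
  expect_equal(h0$count, rep(0L, 5))
  # merging the first two bins conserves totals
  r2 <- make_reports(50, onset = sample.int(500, 50, replace = TRUE))
  h2 <- onset_histogram(r2, 50)
  expect_equal(sum(h2$count), 50)
})

test_that("cumulative curve is monotone, ends at 1, handles point masses", {
  r <- make_reports(3, onset = c(0, 0, 1))
  cc <- cumulative_curve(r)
  expect_equal(cc$day, c(0, 1))
  expect_equal(cc$cum_fraction, c(2 / 3, 1))
  expect_true(all(diff(cc$cum_fraction) >= 0))
  one <- cumulative_curve(make_reports(1, onset = 5))
  expect_equal(one$cum_fraction, 1)
  expect_error(cumulative_curve(make_reports(2, onset = NA_real_)),
               "no non-missing")
})

test_that("generated onset data put at least half the mass at day <= 1", {
  x <- small_assembled()
  cc <- cumulative_curve(x$asm$reports)
  expect_gte(cc$cum_fraction[cc$day == 1], 0.5)
  # and the tail drags the mean far above the median
  s <- onset_summary(x$asm$reports)
  expect_equal(s$median, 0)
  expect_gt(s$mean, 5 * max(s$median, 1))
})
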
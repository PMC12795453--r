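# 2x2 tables, ROR/CI computation, frequencies, screening and ranking.

test_that("contingency cells count reports, never term repeats", {
  sym <- tibble::tibble(
    report_id = c("r1", "r1", "r2", "r3"),
    preferred_term = c("Pyrexia", "Pyrexia", "Crying", "Pyrexia")
  )
  ct <- build_contingency(sym, c("r1", "r2"), "r3", "Pyrexia")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 0))
  # absent term
  ct0 <- build_contingency(sym, c("r1", "r2"), "r3", "Rash")
  expect_equal(unlist(ct0[c("a", "b", "c", "d")]),
               c(a = 0, b = 2, c = 0, d = 1))
  # overlap is refused
  expect_error(build_contingency(sym, c("r1", "r2"), c("r2", "r3"), "Pyrexia"),
               "overlap")
})

test_that("ROR, SE and Wald CI match the frozen logistic-regression oracle", {
  # oracle: glm(binomial) IRLS fit on the weighted 2x2, z = 1.96
  res <- compute_ror(5, 5, 5, 5)
  expect_equal(res$ror, 1)
  expect_equal(res$se_log, 0.8944271910, tolerance = 1e-9)
  expect_equal(res$ci_low, 0.1732400118, tolerance = 1e-8)
  expect_equal(res$ci_high, 5.7723385576, tolerance = 1e-8)
  expect_false(res$is_signal)
  # proportional table: ror exactly 1
  expect_equal(compute_ror(10, 20, 30, 60)$ror, 1)
})

test_that("zero cells are flagged undefined or continuity-corrected", {
  suppressMessages({
    res <- compute_ror(0, 10, 5, 5)
    expect_true(res$undefined)
    expect_true(is.na(res$ror))
    cc <- compute_ror(0, 10, 5, 5, correction = TRUE)
  })
  expect_false(cc$undefined)
  expect_equal(cc$ror, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("reciprocal symmetry and monotonicity hold", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample.int(50, 4, replace = TRUE)
    r1 <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    r2 <- compute_ror(cells[2], cells[1], cells[4], cells[3])
    expect_equal(r1$ror * r2$ror, 1, tolerance = 1e-12)
  }
  # increasing a strictly increases ror and ci_low
  a <- 1:30
  res <- compute_ror(a, 50, 20, 100)
  expect_true(all(diff(res$ror) > 0))
  expect_true(all(diff(res$ci_low) > 0))
})

test_that("literal signal-rule variant differs from the CI rule as documented", {
  # ror 1.5, wide CI: lower bound < 1 (no signal) but ror - 1.96*se can
  # exceed 1 when se is small relative to ror - 1
  res_ci <- compute_ror(30, 70, 20, 70)
  res_lit <- compute_ror(30, 70, 20, 70, signal_rule = "literal")
  expect_equal(res_ci$ror, res_lit$ror)
  expect_equal(res_lit$is_signal, (res_lit$ror - 1.96 * res_lit$se_log) > 1)
  expect_equal(res_ci$is_signal, res_ci$ci_low > 1)
})

test_that("per-100k frequency uses round-half-up and validates inputs", {
  expect_equal(normalized_frequency(0, 1000), 0L)
  expect_equal(normalized_frequency(1, 2), 50000L)
  # half-up at the .5 boundary: 7/400 * 1e5 = 1750 exactly; 3/800 = 375
  expect_equal(normalized_frequency(3, 800), 375L)
  expect_error(normalized_frequency(1, 0), "positive")
  expect_error(normalized_frequency(5, 4), "n_total")
})

test_that("screening covers every term in the target stratum", {
  sym <- tibble::tibble(
    report_id = c("t1", "t1", "t2", "c1", "c2"),
    preferred_term = c("Pyrexia", "Crying", "Pyrexia", "Pyrexia", "Rash")
  )
  res <- screen_stratum(sym, c("t1", "t2"), c("c1", "c2"), stratum = "s")
  expect_setequal(res$preferred_term, c("Pyrexia", "Crying"))
  expect_equal(res$a[res$preferred_term == "Pyrexia"], 2L)
  expect_equal(res$frequency_per_100k[res$preferred_term == "Pyrexia"],
               100000L)
  # empty target stratum
  expect_equal(nrow(screen_stratum(sym, character(), c("c1"))), 0)
  # overriding the denominator changes only the frequency
  res2 <- screen_stratum(sym, c("t1", "t2"), c("c1", "c2"),
                         stratum_denominator = 4)
  expect_equal(res2$frequency_per_100k[res2$preferred_term == "Pyrexia"],
               50000L)
})

test_that("ranking sorts by count then term, truncating to k", {
  res <- tibble::tibble(preferred_term = c("Pallor", "Crying", "X"),
                        a = c(5L, 5L, 3L))
  top2 <- rank_top(res, 2)
  expect_equal(top2$preferred_term, c("Crying", "Pallor"))
  expect_equal(nrow(rank_top(res, 10)), 3)
  expect_error(rank_top(res, 0), "positive")
})

test_that("screen on generated data recovers the embedded signal", {
  x <- small_assembled()
  coh <- extract_cohort(x$asm$reports, cohort_spec("SYNFLORIX"))
  comp <- comparator_reports(x$asm$reports, cohort_spec("SYNFLORIX"), coh)
  res <- screen_stratum(x$asm$symptoms, coh$report_id, comp$report_id)
  truth <- x$gen$truth$expected_ror
  hhe <- res[res$preferred_term == "Hypotonic-hyporesponsive episode", ]
  expect_true(hhe$is_signal)
  expect_true(hhe$ci_low <=
                truth$expected_ror[truth$preferred_term ==
                                     "Hypotonic-hyporesponsive episode"])
  expect_true(hhe$ci_high >=
                truth$expected_ror[truth$preferred_term ==
                                     "Hypotonic-hyporesponsive episode"])
})
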
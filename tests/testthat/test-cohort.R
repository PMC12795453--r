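# Seriousness classification, age binning, cohort extraction, stratum
# summaries.

test_that("seriousness is the disjunction of the six outcome flags", {
  base <- make_reports(1)
  for (f in c("died", "life_threat", "hospitalized", "hosp_prolonged",
              "disabled", "birth_defect")) {
    r <- base
    r[[f]] <- TRUE
    expect_true(classify_serious(r), label = f)
  }
  expect_false(classify_serious(base))
  expect_error(classify_serious(base[, 1:3]), "flag column")
})

test_that("age groups partition the axis with the published edges", {
  expect_equal(as.character(assign_age_group(
    c(0, 0.25, 1.60, 1.999, 2, 8, 10.99, 11, 18.9, 19, 53, 54.9, 55, 88, NA))),
    c("0-1", "0-1", "0-1", "0-1", "2-10", "2-10", "2-10", "11-18", "11-18",
      "19-54", "19-54", "19-54", ">=55", ">=55", "unknown"))
  # property: every age maps to exactly one group
  ages <- c(runif(200, 0, 100), NA, -3)
  grp <- assign_age_group(ages)
  expect_false(any(is.na(grp)))
  expect_equal(as.character(grp[length(ages) - 1]), "unknown")
  expect_equal(as.character(grp[length(ages)]), "unknown")  # negative age
})

test_that("cohort extraction filters by vaccine pattern and date window", {
  rep10 <- make_reports(10)
  rep5 <- make_reports(5)
  rep5$report_id <- paste0("o", seq_len(5))
  rep5$vaccines <- rep(list("PREVNAR13"), 5)
  all_r <- dplyr::bind_rows(rep10, rep5)
  got <- extract_cohort(all_r, cohort_spec("SYNFLORIX"))
  expect_equal(nrow(got), 10)
  # window excluding all dates -> empty with warning
  expect_warning(
    empty <- extract_cohort(all_r, cohort_spec("SYNFLORIX",
      date_window = c("2001-01-01", "2001-12-31"))),
    "no reports")
  expect_equal(nrow(empty), 0)
  # two patterns matching one report count it once
  multi <- make_reports(1)
  multi$vaccines <- list(c("SYNFLORIX", "INFANRIX"))
  got2 <- extract_cohort(multi, cohort_spec(c("SYNFLORIX", "INFANRIX")))
  expect_equal(nrow(got2), 1)
  # comparator is disjoint from the cohort
  comp <- comparator_reports(all_r, cohort_spec("SYNFLORIX"), got)
  expect_length(intersect(comp$report_id, got$report_id), 0)
  expect_equal(nrow(comp), 5)
})

test_that("stratum summary percentages re-derive from counts", {
  r <- dplyr::bind_rows(
    make_reports(681, sex = "M"),
    make_reports(590, sex = "F"),
    make_reports(433, sex = "U")
  )
  r$report_id <- sprintf("p%04d", seq_len(nrow(r)))
  r$serious[seq_len(835)] <- TRUE
  s <- summarize_stratum(r, "overall")
  expect_equal(s$n_reports, 1704)
  expect_equal(s$pct_male, 40.0)
  expect_equal(s$pct_female, 34.6)
  expect_equal(s$pct_sex_unknown, 25.4)
  expect_equal(s$pct_serious, 49.0)
  expect_equal(s$n_female + s$n_male + s$n_sex_unknown, s$n_reports)
})

test_that("single-report stratum reports degenerate dispersion", {
  s <- summarize_stratum(make_reports(1, age = 0.25, onset = 2), "one")
  expect_equal(s$age_mean, 0.25)
  expect_equal(s$age_median, 0.25)
  expect_equal(s$age_min, 0.25)
  expect_equal(s$age_max, 0.25)
  expect_equal(s$age_sd, 0)
  expect_true(s$sd_degenerate)
  s0 <- summarize_stratum(make_reports(0), "empty")
  expect_equal(s0$n_reports, 0)
  expect_true(is.na(s0$pct_serious))
})

test_that("baseline table partitions the cohort and keeps the overall row", {
  x <- small_assembled()
  coh <- extract_cohort(x$asm$reports, cohort_spec("SYNFLORIX"))
  bt <- baseline_table(coh)
  per_group <- bt$n_reports[bt$stratum != "overall"]
  expect_equal(sum(per_group), bt$n_reports[bt$stratum == "overall"])
  # serious/non-serious partition and death subset on real generated data
  expect_equal(sum(coh$serious) + sum(!coh$serious), nrow(coh))
  expect_true(all(coh$serious[coh$died]))
})
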
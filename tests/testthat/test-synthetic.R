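# Synthetic VAERS generator: determinism, calibration, ground truth.

test_that("generation is deterministic under seed and distinct across seeds", {
  cfg <- small_config(seed = 21L, n_target = 150L, n_comp = 300L)
  g1 <- generate_vaers(cfg)
  g2 <- generate_vaers(cfg)
  expect_identical(g1$data, g2$data)
  expect_identical(g1$symptoms, g2$symptoms)
  expect_identical(g1$vax, g2$vax)
  g3 <- generate_vaers(small_config(seed = 22L, n_target = 150L,
                                    n_comp = 300L))
  expect_false(identical(g1$data, g3$data))
  # byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(g1, d1)
  p2 <- write_fixture(g2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("config validation rejects infeasible settings", {
  expect_error(generator_config(pts_per_report = rep(0, 5)), "no mass")
  expect_error(generator_config(sex_probs = c(F = 0.9, M = 0.9, U = 0.1)))
  expect_error(generator_config(p_serious = 1.3))
  # signal term colliding with the background catalog
  sp <- default_signal_pts()
  sp$preferred_term[1] <- "Crying"
  expect_error(generator_config(signal_pts = sp), "catalog")
})

test_that("default calibration hits the configured marginals", {
  gen <- generate_vaers(generator_config(seed = 4L))
  truth <- gen$truth$reports
  syn <- truth[truth$vaccine == "SYNFLORIX", ]
  expect_equal(nrow(syn), 1704)
  # serious count within the binomial 99% interval around 0.49 * 1704
  bounds <- qbinom(c(0.005, 0.995), 1704, 0.49)
  expect_gte(sum(syn$serious), bounds[1])
  expect_lte(sum(syn$serious), bounds[2])
  # onset missingness near 17.8%
  expect_equal(mean(is.na(truth$onset_days)), 0.178, tolerance = 0.05)
  # default config has no 11-18-year-olds
  expect_equal(sum(syn$age_group == "11-18"), 0)
  # every report carries 1+ terms
  expect_true(all(truth$n_pts >= 1))
})

test_that("realized marginals converge to configured values at large n", {
  cfg <- generator_config(
    seed = 6L,
    vaccines = list(SYNFLORIX = list(n_reports = 20000L, vax_type = "PNC10",
                                     vax_name = "SYNFLORIX"))
  )
  truth <- generate_vaers(cfg)$truth$reports
  n <- nrow(truth)
  within3sig <- function(obs_p, p) {
    abs(obs_p - p) <= 3 * sqrt(p * (1 - p) / n)
  }
  expect_true(within3sig(mean(truth$serious), 0.49))
  expect_true(within3sig(mean(truth$sex == "M"), 0.400))
  expect_true(within3sig(mean(is.na(truth$onset_days)), 0.178))
  expect_true(within3sig(mean(truth$age_group == "0-1"), 1054 / 1704))
  # onset point mass at day 0 matches pi0 * p0_within
  expect_true(within3sig(mean(truth$onset_days == 0, na.rm = TRUE),
                         0.7 * 0.75))
})

test_that("truth record's expected ROR equals the brute-force odds ratio", {
  cfg <- generator_config(seed = 2L)
  er <- generate_vaers(cfg)$truth$expected_ror
  sp <- cfg$signal_pts
  for (i in seq_len(nrow(sp))) {
    brute <- (sp$p_target[i] / (1 - sp$p_target[i])) /
      (sp$p_comparator[i] / (1 - sp$p_comparator[i]))
    expect_equal(er$expected_ror[er$preferred_term == sp$preferred_term[i]],
                 brute, tolerance = 1e-12)
  }
})

test_that("empty config yields header-only files", {
  cfg <- generator_config(
    vaccines = list(SYNFLORIX = list(n_reports = 0L, vax_type = "PNC10",
                                     vax_name = "SYNFLORIX")))
  gen <- generate_vaers(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(gen, dir)
  expect_equal(length(readLines(paths[["data"]])), 1)
  expect_equal(length(readLines(paths[["vax"]])), 1)
})

test_that("casing noise is absorbed by canonicalization", {
  cfg <- small_config(seed = 31L, n_target = 200L, n_comp = 200L)
  cfg$casing_noise <- TRUE
  gen <- generate_vaers(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(gen, dir)
  asm <- suppressMessages(suppressWarnings(
    vaers_assemble(read_vaers_data(paths[["data"]]),
                   read_vaers_symptoms(paths[["symptoms"]]),
                   read_vaers_vax(paths[["vax"]]))))
  expect_equal(nrow(asm$reports), nrow(gen$truth$reports))
  expect_equal(nrow(asm$symptoms), sum(gen$truth$reports$n_pts))
  # no case-duplicate terms survive
  pts <- unique(asm$symptoms$preferred_term)
  expect_equal(anyDuplicated(tolower(pts)), 0)
})
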
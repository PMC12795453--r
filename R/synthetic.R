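# Seeded generator of VAERS-format report triplets with known ground truth.
#
# The generative model, per report:
#   vaccine      fixed by the per-vaccine report counts in the config
#   age group    categorical mixture (infant-dominated by default), with a
#                within-group age law per group
#   sex          categorical F/M/U
#   serious      Bernoulli(p_serious); deaths are a Bernoulli subset of the
#                serious reports, and every death sets the DIED flag
#   onset days   missing with prob p_onset_missing; else a two-part mixture:
#                with prob pi0 a point mass on {0, 1} (weighted toward 0 so
#                the median lands at 0), otherwise 2 + a geometric tail whose
#                mean makes the overall mean far exceed the median — the
#                signature shape of spontaneous-report onset data
#   terms        K ~ pts_per_report on 1..5 background terms sampled without
#                replacement from the age-group catalog, plus independent
#                per-report Bernoulli draws for each "signal" term
#
# Signal terms are the ground-truth carriers: a signal term never appears in
# the background catalog, so its per-report occurrence probability is exactly
# the configured Bernoulli probability, and the generating reporting odds
# ratio between two vaccines is a closed form stored in the truth record.

#' Configuration for the synthetic VAERS generator
#'
#' Defaults emulate a mid-sized pediatric-vaccine report population: 1,704
#' target-vaccine reports against a 10,000-report comparator universe; 49%
#' serious; sex split F/M/unknown = 0.346/0.400/0.254; an infant-dominated
#' age mixture (expected group sizes 1054 / 22 / 0 / 13 / 19 with the
#' remainder age-missing); onset concentrated at days 0-1 with a long
#' geometric tail and 17.8% missingness; and four embedded signal terms
#' (hypotonic-hyporesponsive episode, hypotonia, pallor, bronchiolitis)
#' whose target-vs-comparator reporting-rate ratios are known exactly.
#'
#' @param seed Integer seed; every draw is derived from it.
#' @param vaccines Named list: vaccine label -> list(n_reports, vax_type,
#'   vax_name).
#' @param target Label of the target vaccine (receives the ROR overrides).
#' @param p_serious Probability a report is serious.
#' @param p_death_given_serious Probability a serious report is fatal.
#' @param sex_probs Named probabilities for F, M, U; must sum to 1.
#' @param age_group_probs Named probabilities over "0-1", "2-10", "11-18",
#'   "19-54", ">=55", "unknown"; must sum to 1.
#' @param onset_pi0 Weight of the {0, 1} point mass in the onset mixture.
#' @param onset_p0_within Conditional probability of day 0 within the point
#'   mass (> 0.5 keeps the overall median at 0).
#' @param onset_tail_mean Mean of the geometric tail component (days beyond
#'   day 1).
#' @param p_onset_missing Probability the onset interval is missing.
#' @param pts_per_report Probabilities for 1..5 background terms per report.
#' @param pt_catalog Named list: age-group label -> data frame with columns
#'   `preferred_term`, `weight` (background term sampling weights).
#' @param signal_pts Data frame with columns `preferred_term`,
#'   `p_comparator` (per-report Bernoulli probability in every
#'   non-target vaccine) and `p_target` (probability in the target vaccine).
#' @param casing_noise Randomly perturb term casing/whitespace in the
#'   written files (exercises canonicalization; default FALSE).
#' @return A validated `generator_config` list. The implied generating
#'   reporting odds ratio per signal term is
#'   `odds(p_target) / odds(p_comparator)`.
#' @export
generator_config <- function(
    seed = 1L,
    vaccines = list(
      SYNFLORIX = list(n_reports = 1704L, vax_type = "PNC10",
                       vax_name = "SYNFLORIX"),
      COMPARATOR = list(n_reports = 10000L, vax_type = "PNC13",
                        vax_name = "PREVNAR13")
    ),
    target = "SYNFLORIX",
    p_serious = 0.49,
    p_death_given_serious = 33 / 835,
    sex_probs = c(F = 0.346, M = 0.400, U = 0.254),
    age_group_probs = c("0-1" = 1054 / 1704, "2-10" = 22 / 1704,
                        "11-18" = 0, "19-54" = 13 / 1704,
                        ">=55" = 19 / 1704, "unknown" = 596 / 1704),
    onset_pi0 = 0.7,
    onset_p0_within = 0.75,
    onset_tail_mean = 28,
    p_onset_missing = 0.178,
    pts_per_report = c(0.45, 0.30, 0.15, 0.07, 0.03),
    pt_catalog = default_pt_catalog(),
    signal_pts = default_signal_pts(),
    casing_noise = FALSE) {
  probs_ok <- function(p) all(p >= 0 & p <= 1) && abs(sum(p) - 1) < 1e-8
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    length(vaccines) >= 1,
    target %in% names(vaccines),
    all(vapply(vaccines, function(v) v$n_reports >= 0, logical(1))),
    p_serious >= 0, p_serious <= 1,
    p_death_given_serious >= 0, p_death_given_serious <= 1,
    probs_ok(sex_probs), probs_ok(age_group_probs),
    onset_pi0 >= 0, onset_pi0 <= 1,
    p_onset_missing >= 0, p_onset_missing <= 1,
    length(pts_per_report) == 5
  )
  if (sum(pts_per_report) <= 0) {
    stop("pts_per_report has no mass", call. = FALSE)
  }
  pts_per_report <- pts_per_report / sum(pts_per_report)
  if (!setequal(names(age_group_probs),
                c("0-1", "2-10", "11-18", "19-54", ">=55", "unknown"))) {
    stop("age_group_probs must cover the six age-group labels", call. = FALSE)
  }
  if (nrow(signal_pts)) {
    stopifnot(all(signal_pts$p_comparator >= 0 & signal_pts$p_comparator < 1),
              all(signal_pts$p_target >= 0 & signal_pts$p_target < 1))
    catalog_pts <- tolower(unlist(lapply(pt_catalog, function(df)
      df$preferred_term)))
    clash <- intersect(tolower(signal_pts$preferred_term), catalog_pts)
    if (length(clash)) {
      stop("signal term(s) also present in the background catalog: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed), vaccines = vaccines, target = target,
    p_serious = p_serious, p_death_given_serious = p_death_given_serious,
    sex_probs = sex_probs, age_group_probs = age_group_probs,
    onset_pi0 = onset_pi0, onset_p0_within = onset_p0_within,
    onset_tail_mean = onset_tail_mean, p_onset_missing = p_onset_missing,
    pts_per_report = pts_per_report, pt_catalog = pt_catalog,
    signal_pts = tibble::as_tibble(signal_pts), casing_noise = casing_noise
  ), class = "generator_config")
}

#' Default background preferred-term catalog by age group
#'
#' Age-specific term profiles: infants report systemic reactions (crying,
#' fever, vomiting, apnoea), toddlers and children injection/vaccination
#' site reactions and motor complaints, adults and the elderly localized
#' reactions. Weights are relative sampling weights within a group.
#'
#' @return Named list of data frames (`preferred_term`, `weight`).
#' @export
default_pt_catalog <- function() {
  infant <- tibble::tibble(
    preferred_term = c("Crying", "Pyrexia", "Vomiting", "Diarrhoea",
                       "Somnolence", "Decreased appetite", "Restlessness",
                       "Apnoea", "Irritability", "Screaming",
                       "Injection site erythema", "Erythema", "Urticaria",
                       "Convulsion", "Cyanosis"),
    weight = c(30, 28, 9, 8, 7, 7, 6, 4, 4, 3, 3, 2, 2, 2, 1)
  )
  child <- tibble::tibble(
    preferred_term = c("Crying", "Pyrexia", "Gait disturbance",
                       "Pain in extremity", "Injection site erythema",
                       "Vaccination site reaction", "Vaccination site oedema",
                       "Vomiting", "Vaccination site nodule", "Urticaria"),
    weight = c(9, 8, 5, 4, 3, 3, 2, 2, 2, 1)
  )
  adult <- tibble::tibble(
    preferred_term = c("Injection site swelling", "Erythema", "Malaise",
                       "Oedema peripheral", "Headache", "Pain in extremity",
                       "Chills", "Pyrexia", "Vaccination site erythema",
                       "Vaccination site pain"),
    weight = c(4, 4, 4, 3, 3, 3, 3, 3, 2, 2)
  )
  elderly <- tibble::tibble(
    preferred_term = c("Erythema", "Injection site erythema", "Swelling",
                       "Pyrexia", "Pain in extremity",
                       "Injection site swelling", "Peripheral swelling",
                       "Dizziness", "Pain", "Chills"),
    weight = c(7, 5, 4, 4, 4, 3, 3, 2, 2, 2)
  )
  list("0-1" = infant, "2-10" = child, "11-18" = child,
       "19-54" = adult, ">=55" = elderly, "unknown" = infant)
}

#' Default embedded signal terms
#'
#' Comparator rates follow a large pneumococcal-vaccine report universe
#' (about 1.0% hypotonic-hyporesponsive episode, 2.6% hypotonia, 3.1%
#' pallor, 0.18% bronchiolitis); target rates are elevated to the
#' per-report shares observed for the target vaccine (17.7%, 8.5%, 9.2%,
#' 4.2%), giving generating odds ratios of roughly 21, 3.5, 3.2 and 24.
#'
#' @return Tibble with columns `preferred_term`, `p_comparator`, `p_target`.
#' @export
default_signal_pts <- function() {
  tibble::tibble(
    preferred_term = c("Hypotonic-hyporesponsive episode", "Hypotonia",
                       "Pallor", "Bronchiolitis"),
    p_comparator = c(431 / 43273, 1113 / 43273, 1338 / 43273, 77 / 43273),
    p_target = c(302 / 1704, 145 / 1704, 156 / 1704, 71 / 1704)
  )
}

# Generating odds ratio for each signal term of a config.
expected_ror_table <- function(config) {
  sp <- config$signal_pts
  if (!nrow(sp)) {
    return(tibble::tibble(vaccine = character(), preferred_term = character(),
                          p_target = numeric(), p_comparator = numeric(),
                          expected_ror = numeric()))
  }
  odds <- function(p) p / (1 - p)
  tibble::tibble(
    vaccine = config$target,
    preferred_term = sp$preferred_term,
    p_target = sp$p_target,
    p_comparator = sp$p_comparator,
    expected_ror = odds(sp$p_target) / odds(sp$p_comparator)
  )
}

# Within-group age laws (years).
sample_age <- function(group, n) {
  switch(group,
    "0-1" = pmin(pmax(stats::rlnorm(n, log(0.25), 0.7), 0.01), 1.99),
    "2-10" = pmin(2 + floor(stats::rexp(n, rate = 1)), 8),
    "11-18" = stats::runif(n, 11, 18.99),
    "19-54" = round(stats::runif(n, 19, 53.99), 0),
    ">=55" = pmin(round(55 + stats::rexp(n, rate = 1 / 12), 0), 88),
    "unknown" = rep(NA_real_, n)
  )
}

# Onset mixture: point mass on {0,1} + shifted geometric tail.
sample_onset <- function(n, config) {
  tail_draw <- 2 + stats::rgeom(n, prob = 1 / (config$onset_tail_mean - 1))
  early <- stats::rbinom(n, 1, config$onset_pi0) == 1
  day01 <- stats::rbinom(n, 1, 1 - config$onset_p0_within)
  onset <- ifelse(early, day01, tail_draw)
  onset[stats::rbinom(n, 1, config$p_onset_missing) == 1] <- NA_real_
  onset
}

#' Generate a synthetic VAERS triplet
#'
#' Deterministic given `config$seed`: the same config yields identical
#' tables (and, via [write_fixture()], byte-identical files). The returned
#' truth record carries each report's latent stratum and the exact
#' generating reporting odds ratio for every signal term.
#'
#' @param config A [generator_config()].
#' @return List with elements `data`, `symptoms`, `vax` (character tibbles
#'   in the VAERS CSV dialect) and `truth`, itself a list of `reports`
#'   (report_id, vaccine, age_group, age_years, sex, serious, died,
#'   onset_days, n_pts) and `expected_ror` (vaccine, preferred_term,
#'   p_target, p_comparator, expected_ror).
#' @export
generate_vaers <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  vaccine_labels <- names(config$vaccines)
  n_per <- vapply(config$vaccines, function(v) as.integer(v$n_reports),
                  integer(1))
  n <- sum(n_per)
  if (n == 0) {
    empty <- tibble::tibble()
    return(list(
      data = tibble::as_tibble(stats::setNames(
        as.list(rep(list(character()), length(.data_cols))), .data_cols)),
      symptoms = tibble::as_tibble(stats::setNames(
        as.list(rep(list(character()), 11)),
        c("VAERS_ID", paste0("SYMPTOM", 1:5), paste0("SYMPTOMVERSION", 1:5)))),
      vax = tibble::as_tibble(stats::setNames(
        as.list(rep(list(character()), 3)), .vax_cols)),
      truth = list(reports = empty, expected_ror = expected_ror_table(config))
    ))
  }

  vaccine <- rep(vaccine_labels, n_per)
  report_id <- sprintf("%07d", seq_len(n))

  group_levels <- names(config$age_group_probs)
  age_group <- sample(group_levels, n, replace = TRUE,
                      prob = config$age_group_probs)
  age_years <- rep(NA_real_, n)
  for (g in group_levels) {
    idx <- which(age_group == g)
    if (length(idx)) age_years[idx] <- sample_age(g, length(idx))
  }

  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  serious <- stats::rbinom(n, 1, config$p_serious) == 1
  died <- serious & stats::rbinom(n, 1, config$p_death_given_serious) == 1

  # flag pattern: deaths set DIED; other serious reports draw one primary
  # flag, dominated by hospitalization
  flag <- rep("none", n)
  flag[died] <- "died"
  other_serious <- which(serious & !died)
  if (length(other_serious)) {
    flag[other_serious] <- sample(
      c("hospitalized", "life_threat", "disabled", "hosp_prolonged",
        "birth_defect"),
      length(other_serious), replace = TRUE,
      prob = c(0.78, 0.10, 0.07, 0.03, 0.02))
  }

  onset <- sample_onset(n, config)

  # dates: receive within the 2010-2024 window; vaccination shortly before
  window <- as.Date(c("2010-01-01", "2024-12-30"))
  receive_date <- window[1] +
    sample.int(as.integer(window[2] - window[1]) + 1L, n, replace = TRUE) - 1L
  vax_date <- receive_date - sample.int(60L, n, replace = TRUE)
  onset_date <- vax_date + ifelse(is.na(onset), NA_real_, onset)

  # background terms
  catalog_for <- function(g) config$pt_catalog[[g]] %||% config$pt_catalog[[1]]
  k_bg <- sample.int(5L, n, replace = TRUE, prob = config$pts_per_report)
  bg_pts <- vector("list", n)
  for (i in seq_len(n)) {
    cat_i <- catalog_for(age_group[i])
    k <- min(k_bg[i], nrow(cat_i))
    bg_pts[[i]] <- sample(cat_i$preferred_term, k, prob = cat_i$weight)
  }

  # signal terms: independent Bernoulli per report, probability by vaccine
  sp <- config$signal_pts
  sig_pts <- rep(list(character()), n)
  if (nrow(sp)) {
    is_target <- vaccine == config$target
    for (j in seq_len(nrow(sp))) {
      p <- ifelse(is_target, sp$p_target[j], sp$p_comparator[j])
      hit <- stats::rbinom(n, 1, p) == 1
      for (i in which(hit)) sig_pts[[i]] <- c(sig_pts[[i]], sp$preferred_term[j])
    }
  }

  # combine; reports with more than five terms spill onto continuation
  # rows in the symptoms file, as in the real archives
  pts <- mapply(function(bg, sg) unique(c(sg, bg)), bg_pts, sig_pts,
                SIMPLIFY = FALSE)

  flag_col <- function(what) {
    ifelse(flag == what | (what == "died" & died), "Y", "")
  }
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%m/%d/%Y"))
  data_tbl <- tibble::tibble(
    VAERS_ID = report_id,
    RECVDATE = fmt_date(receive_date),
    AGE_YRS = ifelse(is.na(age_years), "",
                     formatC(age_years, format = "fg", digits = 4)),
    SEX = ifelse(sex == "U", "", sex),
    DIED = flag_col("died"),
    L_THREAT = flag_col("life_threat"),
    HOSPITAL = flag_col("hospitalized"),
    X_STAY = flag_col("hosp_prolonged"),
    DISABLE = flag_col("disabled"),
    BIRTH_DEFECT = flag_col("birth_defect"),
    NUMDAYS = ifelse(is.na(onset), "", format(onset, scientific = FALSE,
                                              trim = TRUE)),
    VAX_DATE = fmt_date(vax_date),
    ONSET_DATE = fmt_date(onset_date)
  )

  # symptoms file: chunk each report's terms into rows of five
  sym_rows <- lapply(seq_len(n), function(i) {
    p <- pts[[i]]
    if (config$casing_noise) {
      flip <- stats::rbinom(length(p), 1, 0.2) == 1
      p[flip] <- paste0(" ", toupper(p[flip]), " ")
    }
    n_rows <- ceiling(length(p) / 5)
    out <- matrix(c(p, rep("", n_rows * 5 - length(p))), nrow = n_rows,
                  ncol = 5, byrow = TRUE)
    cbind(VAERS_ID = report_id[i], out)
  })
  sym_mat <- do.call(rbind, sym_rows)
  symptoms_tbl <- tibble::as_tibble(as.data.frame(sym_mat,
                                                  stringsAsFactors = FALSE))
  names(symptoms_tbl) <- c("VAERS_ID", paste0("SYMPTOM", 1:5))
  for (j in 1:5) {
    symptoms_tbl[[paste0("SYMPTOMVERSION", j)]] <-
      ifelse(symptoms_tbl[[paste0("SYMPTOM", j)]] == "", "", "27.0")
  }

  vax_tbl <- tibble::tibble(
    VAERS_ID = report_id,
    VAX_TYPE = vapply(vaccine, function(v) config$vaccines[[v]]$vax_type,
                      character(1)),
    VAX_NAME = vapply(vaccine, function(v) config$vaccines[[v]]$vax_name,
                      character(1))
  )

  truth_reports <- tibble::tibble(
    report_id = report_id, vaccine = vaccine, age_group = age_group,
    age_years = age_years, sex = sex, serious = serious, died = died,
    onset_days = onset, n_pts = lengths(pts)
  )

  list(data = data_tbl, symptoms = symptoms_tbl, vax = vax_tbl,
       truth = list(reports = truth_reports,
                    expected_ror = expected_ror_table(config)))
}

#' Write a generated triplet as VAERS-dialect CSV files
#'
#' Emits `VAERSDATA.csv`, `VAERSSYMPTOMS.csv`, `VAERSVAX.csv` and two
#' ground-truth TSVs (`truth_reports.tsv`, `truth_ror.tsv`) into
#' `directory`, creating it if needed. Empty configs yield header-only
#' files.
#'
#' @param generated Output of [generate_vaers()].
#' @param directory Target directory.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_fixture <- function(generated, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory, call. = FALSE)
    }
  }
  paths <- c(
    data = file.path(directory, "VAERSDATA.csv"),
    symptoms = file.path(directory, "VAERSSYMPTOMS.csv"),
    vax = file.path(directory, "VAERSVAX.csv"),
    truth_reports = file.path(directory, "truth_reports.tsv"),
    truth_ror = file.path(directory, "truth_ror.tsv")
  )
  readr::write_csv(generated$data, paths["data"], progress = FALSE)
  readr::write_csv(generated$symptoms, paths["symptoms"], progress = FALSE)
  readr::write_csv(generated$vax, paths["vax"], progress = FALSE)
  readr::write_tsv(generated$truth$reports, paths["truth_reports"],
                   progress = FALSE)
  readr::write_tsv(generated$truth$expected_ror, paths["truth_ror"],
                   progress = FALSE)
  invisible(paths)
}
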
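# Seriousness classification, age binning, cohort extraction and stratum
# summaries.

# Age-group bin table. "0-1" runs to just under 2 years, "2-10" to just under
# 11, and so on; these edges are forced by the observed per-group age ranges
# (max 1.60 in the infant group, max 8.00 in 2-10, min 55 in the oldest).
age_group_levels <- c("0-1", "2-10", "11-18", "19-54", ">=55", "unknown")

#' Classify report seriousness from the structured outcome flags
#'
#' A report is serious when any regulatory outcome flag is set: death,
#' life-threatening condition, inpatient hospitalization or prolongation of
#' an existing hospitalization, persistent or significant disability, or
#' congenital anomaly (the 21 CFR 600.80 definition). Emergency-room visits
#' are deliberately not a criterion, and the "medically important" clause
#' of the regulation is not derivable from structured fields, so the flags
#' alone define the contract.
#'
#' @param reports A data frame with logical columns `died`, `life_threat`,
#'   `hospitalized`, `hosp_prolonged`, `disabled`, `birth_defect`.
#' @return Logical vector, one element per row.
#' @export
classify_serious <- function(reports) {
  flags <- c("died", "life_threat", "hospitalized", "hosp_prolonged",
             "disabled", "birth_defect")
  missing_cols <- setdiff(flags, names(reports))
  if (length(missing_cols)) {
    stop("missing seriousness flag column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- rep(FALSE, nrow(reports))
  for (f in flags) {
    v <- reports[[f]]
    v[is.na(v)] <- FALSE
    out <- out | v
  }
  out
}

#' Assign an age group label
#'
#' Bins age in years into the study's groups: `[0,2)` -> "0-1",
#' `[2,11)` -> "2-10", `[11,19)` -> "11-18", `[19,55)` -> "19-54",
#' `[55, Inf)` -> ">=55"; missing (or negative, treated upstream as missing)
#' ages map to "unknown". The bins partition the age axis, so every report
#' receives exactly one label.
#'
#' @param age_years Numeric vector of ages in years, `NA` allowed.
#' @return Factor with levels "0-1", "2-10", "11-18", "19-54", ">=55",
#'   "unknown".
#' @examples
#' assign_age_group(c(0.25, 1.6, 2, 54.9, 55, NA))
#' @export
assign_age_group <- function(age_years) {
  age_years[!is.na(age_years) & age_years < 0] <- NA_real_
  idx <- findInterval(age_years, c(0, 2, 11, 19, 55))
  lab <- age_group_levels[idx]
  lab[is.na(age_years)] <- "unknown"
  factor(lab, levels = age_group_levels)
}

#' Define a study cohort
#'
#' @param vaccine_match Character vector of vaccine name/type patterns
#'   (regular expressions, matched case-insensitively against both `vax_name`
#'   and `vax_type`). Must be non-empty.
#' @param date_window Length-2 vector coercible to `Date`: inclusive
#'   `[start, end]` window on the report receive date, or `NULL` for no
#'   restriction.
#' @param comparator `"all_other_reports"` (default) or a character vector of
#'   vaccine patterns naming the comparator set.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(vaccine_match, date_window = NULL,
                        comparator = "all_other_reports") {
  stopifnot(length(vaccine_match) >= 1)
  if (!is.null(date_window)) {
    date_window <- as.Date(date_window)
    stopifnot(length(date_window) == 2, date_window[1] <= date_window[2])
  }
  structure(list(vaccine_match = vaccine_match, date_window = date_window,
                 comparator = comparator),
            class = "cohort_spec")
}

# TRUE where a report's vaccine set matches any pattern.
match_vaccines <- function(reports, patterns) {
  hit_one <- function(vaxnames, vaxtypes) {
    any(vapply(patterns, function(p) {
      any(grepl(p, vaxnames, ignore.case = TRUE)) ||
        any(grepl(p, vaxtypes, ignore.case = TRUE))
    }, logical(1)))
  }
  mapply(hit_one, reports$vaccines, reports$vax_types)
}

#' Extract a cohort of reports
#'
#' Filters the assembled report table to reports whose vaccine set matches
#' the spec's patterns and whose receive date falls inside the window. A
#' report matching several patterns is counted once (set semantics).
#'
#' @param reports Report tibble from [vaers_assemble()].
#' @param spec A [cohort_spec()].
#' @return The matching subset of `reports`; warns if empty.
#' @export
extract_cohort <- function(reports, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  keep <- match_vaccines(reports, spec$vaccine_match)
  if (!is.null(spec$date_window)) {
    keep <- keep & !is.na(reports$receive_date) &
      reports$receive_date >= spec$date_window[1] &
      reports$receive_date <= spec$date_window[2]
  }
  out <- reports[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("cohort extraction returned no reports", call. = FALSE)
  }
  out
}

#' Comparator report set for a cohort
#'
#' @param reports Full assembled report table.
#' @param spec A [cohort_spec()].
#' @param cohort The extracted cohort (recomputed if omitted).
#' @return Tibble of comparator reports, disjoint from the cohort.
#' @export
comparator_reports <- function(reports, spec, cohort = NULL) {
  if (is.null(cohort)) cohort <- extract_cohort(reports, spec)
  rest <- reports[!reports$report_id %in% cohort$report_id, , drop = FALSE]
  if (identical(spec$comparator, "all_other_reports")) {
    return(rest)
  }
  rest[match_vaccines(rest, spec$comparator), , drop = FALSE]
}

# Descriptive block for one numeric vector: mean, sd, median, min, max.
num_block <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                min = NA_real_, max = NA_real_))
  }
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else 0,
       median = stats::median(x), min = min(x), max = max(x))
}

#' Summarize one report stratum
#'
#' Baseline characteristics of a report subset in the shape of a published
#' cohort table: sex counts with percentages, age and onset-interval
#' descriptives, onset missingness, and the serious share. Percentages use
#' the stratum size as denominator and round half up to one decimal, so the
#' printed values re-derive exactly from the counts.
#'
#' @param reports Report tibble (a stratum subset).
#' @param label Stratum label carried into the output.
#' @return A one-row tibble with columns `stratum`, `n_reports`,
#'   `n_female`/`pct_female`, `n_male`/`pct_male`, `n_sex_unknown`/
#'   `pct_sex_unknown`, `age_mean`, `age_sd`, `age_median`, `age_min`,
#'   `age_max`, `onset_mean`, `onset_sd`, `onset_median`, `onset_min`,
#'   `onset_max`, `n_onset_missing`, `pct_onset_missing`, `n_serious`,
#'   `pct_serious`, and `sd_degenerate` (TRUE when a dispersion was reported
#'   as 0 for a single observation).
#' @export
summarize_stratum <- function(reports, label = "overall") {
  n <- nrow(reports)
  pct <- function(k) {
    if (n > 0) unname(round_half_up(100 * k / n, 1)) else NA_real_
  }
  sex <- table(factor(reports$sex, levels = c("F", "M", "U")))
  age <- num_block(reports$age_years)
  onset <- num_block(reports$onset_interval_days)
  n_serious <- sum(reports$serious)
  tibble::tibble(
    stratum = label,
    n_reports = n,
    n_female = unname(sex["F"]), pct_female = pct(sex["F"]),
    n_male = unname(sex["M"]), pct_male = pct(sex["M"]),
    n_sex_unknown = unname(sex["U"]), pct_sex_unknown = pct(sex["U"]),
    age_mean = age$mean, age_sd = age$sd, age_median = age$median,
    age_min = age$min, age_max = age$max,
    onset_mean = onset$mean, onset_sd = onset$sd,
    onset_median = onset$median, onset_min = onset$min,
    onset_max = onset$max,
    n_onset_missing = n - onset$n,
    pct_onset_missing = pct(n - onset$n),
    n_serious = n_serious, pct_serious = pct(n_serious),
    sd_degenerate = (age$n == 1) || (onset$n == 1)
  )
}

#' Baseline table across age groups
#'
#' [summarize_stratum()] applied per age group plus the overall column; the
#' overall row includes age-unknown reports, so per-group ns need not sum to
#' the overall n.
#'
#' @param reports Report tibble.
#' @param drop_empty Drop age groups with zero reports (default FALSE).
#' @return Tibble with one row per age group plus `"overall"`.
#' @export
baseline_table <- function(reports, drop_empty = FALSE) {
  grp <- assign_age_group(reports$age_years)
  rows <- lapply(age_group_levels, function(g) {
    sub <- reports[!is.na(grp) & grp == g, , drop = FALSE]
    summarize_stratum(sub, g)
  })
  out <- dplyr::bind_rows(c(rows, list(summarize_stratum(reports, "overall"))))
  if (drop_empty) out <- out[out$n_reports > 0 | out$stratum == "overall", ]
  out
}
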
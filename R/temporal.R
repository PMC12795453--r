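# Time-to-onset summaries, binned onset histograms and cumulative curves.

# Fixed onset bins (integer days, closed on both ends): 0-30, 31-90, 91-180,
# 181-360, >360.
onset_bin_labels <- c("0-30", "31-90", "91-180", "181-360", ">360")

#' Time-to-onset summary for one preferred term and stratum
#'
#' Median and quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7); the mean is reported alongside because
#' spontaneous-report onset distributions are heavily right-skewed (a few
#' reports arrive years after vaccination) and mean and median tell
#' different stories. Missing onsets are counted, never imputed.
#'
#' @param reports Report tibble with `onset_interval_days`.
#' @param symptoms Long (report_id, preferred_term) table; `NULL` to
#'   summarize all reports regardless of term.
#' @param pt Preferred term to restrict to (case-insensitive); `NULL` for
#'   all terms.
#' @param stratum Label carried into the output.
#' @return One-row tibble: `preferred_term`, `stratum`, `n` (non-missing
#'   onsets), `n_missing`, `mean`, `median`, `q1`, `q3`, `undefined` (TRUE
#'   when no non-missing onset exists and the statistics are `NA`).
#' @export
onset_summary <- function(reports, symptoms = NULL, pt = NULL,
                          stratum = "all") {
  sub <- reports
  if (!is.null(pt)) {
    stopifnot(!is.null(symptoms))
    key <- tolower(canonicalize_pt(pt))
    ids <- unique(symptoms$report_id[tolower(symptoms$preferred_term) == key])
    sub <- sub[sub$report_id %in% ids, , drop = FALSE]
  }
  x <- sub$onset_interval_days
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(tibble::tibble(preferred_term = pt %||% "(all)", stratum = stratum,
                          n = 0L, n_missing = n_missing, mean = NA_real_,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          undefined = TRUE))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(preferred_term = pt %||% "(all)", stratum = stratum,
                 n = length(x), n_missing = n_missing, mean = mean(x),
                 median = q[2], q1 = q[1], q3 = q[3], undefined = FALSE)
}

#' Binned onset histogram with per-100,000 frequencies
#'
#' Counts non-missing onsets into the fixed day intervals 0-30, 31-90,
#' 91-180, 181-360 and >360 (closed on both ends on integer days: day 30
#' falls in the first bin, day 31 in the second) and normalizes each count
#' per 100,000 reports of the vaccine.
#'
#' @param reports Report tibble with `onset_interval_days`.
#' @param vaccine_total Frequency denominator (total reports for the
#'   vaccine); defaults to `nrow(reports)`.
#' @param vaccine Label carried into the output.
#' @return Tibble with one row per bin: `vaccine`, `bin`, `count`,
#'   `frequency_per_100k`.
#' @export
onset_histogram <- function(reports, vaccine_total = nrow(reports),
                            vaccine = "target") {
  x <- reports$onset_interval_days
  x <- x[!is.na(x)]
  neg <- x < 0
  if (any(neg)) {
    warning(sum(neg), " negative onset value(s) excluded", call. = FALSE)
    x <- x[!neg]
  }
  edges <- c(-Inf, 30, 90, 180, 360, Inf)
  counts <- as.integer(table(cut(x, edges, labels = onset_bin_labels)))
  freq <- if (vaccine_total > 0) {
    normalized_frequency(counts, vaccine_total)
  } else {
    rep(NA_integer_, length(counts))
  }
  tibble::tibble(vaccine = vaccine,
                 bin = factor(onset_bin_labels, levels = onset_bin_labels),
                 count = counts, frequency_per_100k = freq)
}

#' Cumulative onset curve
#'
#' The empirical cumulative fraction of non-missing onsets at or before each
#' observed day: a nondecreasing step function reaching 1 at the maximum
#' onset.
#'
#' @param reports Report tibble with `onset_interval_days`.
#' @param vaccine Label carried into the output.
#' @return Tibble with one row per distinct onset day: `vaccine`, `day`,
#'   `n_le` (reports with onset <= day), `cum_fraction`.
#' @export
cumulative_curve <- function(reports, vaccine = "target") {
  x <- reports$onset_interval_days
  x <- x[!is.na(x) & x >= 0]
  if (!length(x)) stop("no non-missing onsets", call. = FALSE)
  days <- sort(unique(x))
  n_le <- vapply(days, function(d) sum(x <= d), integer(1))
  tibble::tibble(vaccine = vaccine, day = days, n_le = n_le,
                 cum_fraction = n_le / length(x))
}
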
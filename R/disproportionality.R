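# Reporting odds ratio (ROR) disproportionality analysis.
#
# For a target vaccine and one Preferred Term, the 2x2 table against a
# comparator universe is
#
#                       with PT   without PT
#   target vaccine         a          b        (a + b = n target reports)
#   comparator             c          d        (c + d = n comparator)
#
# ROR = ad / bc;  SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d);
# 95% CI = exp(ln ROR +/- 1.96 * SE). A term is a signal when the lower CI
# bound exceeds 1. Cells are report counts: a term repeated on one report
# counts once.

#' Build a 2x2 contingency table for one preferred term
#'
#' @param symptoms Long (report_id, preferred_term) table from
#'   [vaers_assemble()].
#' @param target_ids Character vector of target-cohort report ids.
#' @param comparator_ids Character vector of comparator report ids; must be
#'   disjoint from `target_ids` (overlap would double-count reports).
#' @param pt Preferred term (matched case-insensitively after whitespace
#'   canonicalization).
#' @return A one-row tibble with columns `preferred_term`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(symptoms, target_ids, comparator_ids, pt) {
  overlap <- intersect(target_ids, comparator_ids)
  if (length(overlap)) {
    stop("target and comparator report sets overlap (", length(overlap),
         " id(s)); refusing to double-count", call. = FALSE)
  }
  key <- tolower(canonicalize_pt(pt))
  with_pt <- unique(symptoms$report_id[tolower(symptoms$preferred_term) == key])
  a <- sum(target_ids %in% with_pt)
  c_ <- sum(comparator_ids %in% with_pt)
  tibble::tibble(preferred_term = pt, a = a, b = length(target_ids) - a,
                 c = c_, d = length(comparator_ids) - c_)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' Vectorized over table cells. With any zero cell the Wald statistic is
#' undefined; by default such rows are flagged `undefined = TRUE` with `NA`
#' estimates (and are excluded from signal lists downstream). With
#' `correction = TRUE` the Haldane-Anscombe continuity correction adds 0.5
#' to every cell of the affected tables instead.
#'
#' @param a,b,c,d Cell counts (non-negative integers, recycled).
#' @param correction Apply +0.5 to all four cells of zero-cell tables
#'   (default FALSE).
#' @param z Normal quantile multiplier of the interval. The default is the
#'   literal 1.96 of the published Wald formula, not `qnorm(0.975)`.
#' @param signal_rule `"ci"` (default): signal when the lower CI bound
#'   exceeds 1. `"literal"`: the arithmetic reading
#'   `ror - z * se_log > 1` sometimes seen in print; documented alternative,
#'   not recommended.
#' @return Tibble with columns `a`, `b`, `c`, `d`, `ror`, `se_log`,
#'   `ci_low`, `ci_high`, `is_signal`, `undefined`.
#' @examples
#' compute_ror(5, 5, 5, 5) # ror 1, CI (0.173, 5.77)
#' @export
compute_ror <- function(a, b, c, d, correction = FALSE, z = 1.96,
                        signal_rule = c("ci", "literal")) {
  signal_rule <- match.arg(signal_rule)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)

  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  undefined <- zero & !correction
  if (correction && any(zero)) {
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
    message(sum(zero), " zero-cell table(s) continuity-corrected (+0.5)")
  } else if (any(undefined)) {
    message(sum(undefined),
            " zero-cell table(s) marked undefined (no continuity correction)")
  }

  ror <- (a * d) / (b * c)
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci_low <- exp(log(ror) - z * se_log)
  ci_high <- exp(log(ror) + z * se_log)
  is_signal <- if (signal_rule == "ci") ci_low > 1 else (ror - z * se_log) > 1

  ror[undefined] <- NA_real_; se_log[undefined] <- NA_real_
  ci_low[undefined] <- NA_real_; ci_high[undefined] <- NA_real_
  is_signal[undefined] <- NA

  tibble::tibble(a = a, b = b, c = c, d = d, ror = ror, se_log = se_log,
                 ci_low = ci_low, ci_high = ci_high, is_signal = is_signal,
                 undefined = undefined)
}

#' Per-100,000 normalized reporting frequency
#'
#' `round_half_up(a / n_total * 100000)` — the scale on which reporting
#' counts are comparable across vaccines with different report volumes.
#'
#' @param a Report count(s) for the event.
#' @param n_total Total reports in the cohort or stratum; must be positive.
#' @return Integer vector of per-100,000 frequencies.
#' @examples
#' normalized_frequency(369, 835) # 44192
#' @export
normalized_frequency <- function(a, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(a < 0 | a > n_total)) {
    stop("event count must lie in [0, n_total]", call. = FALSE)
  }
  as.integer(round_half_up(a / n_total * 1e5))
}

#' Screen every preferred term in a stratum
#'
#' Builds one 2x2 table per term occurring among the target reports and
#' computes ROR, CI, signal flag and the per-100,000 frequency. The
#' frequency denominator defaults to the stratum size, matching the
#' convention that subgroup tables report frequencies within the subgroup.
#'
#' @param symptoms Long (report_id, preferred_term) table.
#' @param target_ids Target stratum report ids.
#' @param comparator_ids Comparator report ids (disjoint).
#' @param stratum_denominator Frequency denominator; defaults to
#'   `length(target_ids)`.
#' @param stratum Label carried into the result.
#' @param ... Passed to [compute_ror()] (`correction`, `signal_rule`, ...).
#' @return Tibble of per-term results sorted by count (desc) then term
#'   (lexicographic): `preferred_term`, `stratum`, `a`, `frequency_per_100k`,
#'   `ror`, `se_log`, `ci_low`, `ci_high`, `is_signal`, `undefined`.
#' @export
screen_stratum <- function(symptoms, target_ids, comparator_ids,
                           stratum_denominator = length(target_ids),
                           stratum = "all", ...) {
  if (length(intersect(target_ids, comparator_ids))) {
    stop("target and comparator report sets overlap", call. = FALSE)
  }
  in_target <- symptoms[symptoms$report_id %in% target_ids, , drop = FALSE]
  if (nrow(in_target) == 0) {
    return(tibble::tibble(preferred_term = character(), stratum = character(),
                          a = integer(), frequency_per_100k = integer(),
                          ror = numeric(), se_log = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          is_signal = logical(), undefined = logical()))
  }
  in_comp <- symptoms[symptoms$report_id %in% comparator_ids, , drop = FALSE]

  a_tab <- dplyr::count(dplyr::distinct(in_target), .data$preferred_term,
                        name = "a")
  c_tab <- dplyr::count(dplyr::distinct(in_comp), .data$preferred_term,
                        name = "c")
  tab <- dplyr::left_join(a_tab, c_tab, by = "preferred_term")
  tab$c[is.na(tab$c)] <- 0L
  tab$b <- length(target_ids) - tab$a
  tab$d <- length(comparator_ids) - tab$c

  res <- compute_ror(tab$a, tab$b, tab$c, tab$d, ...)
  out <- tibble::tibble(
    preferred_term = tab$preferred_term,
    stratum = stratum,
    a = as.integer(tab$a),
    frequency_per_100k = normalized_frequency(tab$a, stratum_denominator),
    ror = res$ror, se_log = res$se_log,
    ci_low = res$ci_low, ci_high = res$ci_high,
    is_signal = res$is_signal, undefined = res$undefined
  )
  out[order(-out$a, out$preferred_term), , drop = FALSE]
}

#' Top-k preferred terms by report count
#'
#' Sorts by count descending with lexicographic tie-break on the term, and
#' truncates to `k` rows.
#'
#' @param results Screen results with columns `a` and `preferred_term`.
#' @param k Number of rows to keep (default 10); must be positive.
#' @return The top `k` rows.
#' @export
rank_top <- function(results, k = 10) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  results <- results[order(-results$a, results$preferred_term), , drop = FALSE]
  utils::head(results, k)
}

#' Format a screen as a publication-style table
#'
#' `ROR(95%CI)` rendered as "x.xx (lo - hi)" to two decimals; undefined
#' rows print "NA".
#'
#' @param results Screen results tibble.
#' @return Tibble with columns `stratum`, `preferred_term`, `count`,
#'   `frequency_per_100k`, `ror_ci`.
#' @export
format_screen <- function(results) {
  fmt <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  ror_ci <- ifelse(results$undefined, "NA",
                   paste0(fmt(results$ror), " (", fmt(results$ci_low), " - ",
                          fmt(results$ci_high), ")"))
  tibble::tibble(stratum = results$stratum,
                 preferred_term = results$preferred_term,
                 count = results$a,
                 frequency_per_100k = results$frequency_per_100k,
                 ror_ci = ror_ci)
}
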
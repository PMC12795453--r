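# Preferred-term -> System Organ Class aggregation.
#
# MedDRA itself is licensed, so the PT -> SOC mapping is user-supplied as a
# two-column delimited file. A small synthetic mapping covering the common
# pediatric-vaccine PTs ships under inst/extdata for offline use.

#' Load a preferred-term to System Organ Class mapping
#'
#' Two-column delimited file (PT, SOC), tab- or comma-separated, header
#' optional (detected by the literal column names "preferred_term"/"soc" or
#' "PT"/"SOC" in the first row). PT keys are whitespace-canonicalized and
#' matched case-insensitively. Duplicate consistent rows collapse; a PT
#' mapped to two different SOCs is an error listing the conflicts.
#'
#' @param path Path to the mapping file.
#' @return Tibble with columns `preferred_term`, `soc`.
#' @export
load_soc_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first)) {
    warning("empty SOC mapping", call. = FALSE)
    return(tibble::tibble(preferred_term = character(), soc = character()))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("preferred_term|^PT[,\t]|[,\t]SOC$", first,
                      ignore.case = FALSE)
  df <- utils::read.delim(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, quote = "\"",
                          col.names = c("preferred_term", "soc"))
  if (nrow(df) == 0) {
    warning("empty SOC mapping", call. = FALSE)
    return(tibble::tibble(preferred_term = character(), soc = character()))
  }
  df$preferred_term <- canonicalize_pt(df$preferred_term)
  df$soc <- canonicalize_pt(df$soc)
  df <- unique(df)
  key <- tolower(df$preferred_term)
  conflicts <- unique(key[duplicated(key)])
  if (length(conflicts)) {
    stop("preferred term(s) mapped to multiple SOCs: ",
         paste(df$preferred_term[match(conflicts, key)], collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' System Organ Class distribution for a stratum
#'
#' Aggregates the long (report, term) table to SOC totals. The counting
#' unit is PT occurrences — (report, term) pairs — not reports, since one
#' report contributes to every SOC its terms map to; percentages are of all
#' mapped occurrences, rounded half up to two decimals. Terms absent from
#' the mapping pool into an `"Unmapped"` row (excluded from the percentage
#' denominator) and are listed in a message.
#'
#' @param symptoms Long (report_id, preferred_term) table.
#' @param stratum_ids Report ids defining the stratum.
#' @param mapping Tibble from [load_soc_mapping()].
#' @return Tibble sorted by count: `soc`, `count`, `pct` (NA for the
#'   Unmapped row).
#' @export
soc_distribution <- function(symptoms, stratum_ids, mapping) {
  sub <- symptoms[symptoms$report_id %in% stratum_ids, , drop = FALSE]
  sub <- dplyr::distinct(sub, .data$report_id, .data$preferred_term)
  idx <- match(tolower(canonicalize_pt(sub$preferred_term)),
               tolower(mapping$preferred_term))
  soc <- mapping$soc[idx]
  unmapped <- is.na(soc)
  if (any(unmapped)) {
    message("unmapped preferred term(s): ",
            paste(sort(unique(sub$preferred_term[unmapped])), collapse = ", "))
  }
  total_mapped <- sum(!unmapped)
  out <- dplyr::count(tibble::tibble(soc = soc[!unmapped]), .data$soc,
                      name = "count", sort = TRUE)
  out$pct <- if (total_mapped > 0) {
    round_half_up(100 * out$count / total_mapped, 2)
  } else {
    numeric(0)
  }
  if (any(unmapped)) {
    out <- dplyr::bind_rows(out, tibble::tibble(soc = "Unmapped",
                                                count = sum(unmapped),
                                                pct = NA_real_))
  }
  out
}
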
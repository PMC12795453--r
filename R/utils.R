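# Shared helpers: commercial rounding and preferred-term canonicalization.

#' Round half away from zero
#'
#' `base::round()` rounds half to even (banker's rounding); report tables in
#' pharmacovigilance publications round half up, so percentages and per-100,000
#' frequencies must too or printed values fail to re-derive from their counts.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5) # 1, where round(0.5) is 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon absorbs representation error in x * scale (e.g. 2.345 * 100)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Canonicalize preferred-term spelling
#'
#' Trims leading/trailing whitespace and collapses internal runs of whitespace
#' to a single space. Case is left untouched here; case-insensitive unification
#' to first-seen casing happens when assembling the long table, where the full
#' set of spellings is visible (see [vaers_assemble()]).
#'
#' @param pt Character vector of preferred terms.
#' @return Character vector with normalized whitespace.
#' @export
canonicalize_pt <- function(pt) {
  gsub("[[:space:]]+", " ", trimws(pt))
}

# Unify casings to first-seen: returns `pt` with every case-insensitive
# duplicate rewritten to the casing of its first occurrence in `pt`.
unify_pt_casing <- function(pt) {
  key <- tolower(pt)
  first <- !duplicated(key)
  lookup <- stats::setNames(pt[first], key[first])
  unname(lookup[key])
}

# Parse VAERS m/d/Y dates; unparseable values become NA without warnings.
parse_vaers_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  as.Date(x, format = "%m/%d/%Y")
}

# VAERS flag fields are "Y" or blank.
parse_flag <- function(x) {
  !is.na(x) & toupper(trimws(as.character(x))) == "Y"
}

# Non-negative numeric parse: unparseable or negative -> NA; returns the
# parsed vector and the count of values invalidated (for logging).
parse_nonneg <- function(x, what, warn = TRUE) {
  raw <- trimws(as.character(x))
  raw[raw == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(raw))
  bad <- (!is.na(raw) & is.na(val)) | (!is.na(val) & val < 0)
  val[bad] <- NA_real_
  if (warn && any(bad)) {
    warning(sprintf("%d unparseable or negative %s value(s) set to missing",
                    sum(bad), what), call. = FALSE)
  }
  val
}

`%||%` <- function(a, b) if (is.null(a)) b else a
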
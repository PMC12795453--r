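# Reading and assembling the VAERS CSV triplet (DATA / SYMPTOMS / VAX).
#
# VAERS distributes yearly CSV triplets keyed by VAERS_ID. The three readers
# below validate headers, coerce the dialect (m/d/Y dates, "Y"/blank flags,
# blank-as-missing numerics) and keep malformed cells as missing rather than
# failing, logging counts via warnings. `vaers_assemble()` joins the triplet
# into the two canonical tables every downstream stage consumes.

# Required headers per file type.
.data_cols <- c("VAERS_ID", "RECVDATE", "AGE_YRS", "SEX", "DIED", "L_THREAT",
                "HOSPITAL", "X_STAY", "DISABLE", "BIRTH_DEFECT", "NUMDAYS",
                "VAX_DATE", "ONSET_DATE")
.symptom_cols <- c("VAERS_ID", paste0("SYMPTOM", 1:5))
.vax_cols <- c("VAERS_ID", "VAX_TYPE", "VAX_NAME")

# Read a VAERS-dialect CSV as all-character columns, UTF-8 with a Latin-1
# fallback (archives mix both encodings across years).
read_vaers_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  read_enc <- function(enc) {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    locale = readr::locale(encoding = enc),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE)
  }
  df <- tryCatch(read_enc("UTF-8"), error = function(e) read_enc("latin1"))
  if (any(grepl("�", unlist(df[1, ]), fixed = TRUE))) {
    df <- read_enc("latin1")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df
}

# Keep the first row per report id, warning with the duplicate count.
drop_dup_ids <- function(df, file_label) {
  dup <- duplicated(df$VAERS_ID)
  if (any(dup)) {
    warning(sprintf("%d duplicate report id(s) in %s; keeping first occurrence",
                    sum(dup), file_label), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read a VAERSDATA file
#'
#' Parses the report-level file of a VAERS triplet: demographics, receive /
#' vaccination / onset dates, the six structured seriousness outcome flags
#' (death, life-threatening, hospitalization, prolonged hospitalization,
#' disability, congenital anomaly) and the onset interval in days (NUMDAYS).
#' Blank flag cells mean `FALSE`; blank, unparseable or negative ages and
#' onset intervals become `NA` with a warning giving the count. Duplicate
#' report ids within the file keep the first row.
#'
#' @param path Path to a VAERSDATA-dialect CSV.
#' @return A tibble with one row per report:
#'   `report_id`, `receive_date`, `age_years`, `sex` ("F", "M" or "U"),
#'   `died`, `life_threat`, `hospitalized`, `hosp_prolonged`, `disabled`,
#'   `birth_defect` (logicals), `onset_interval_days`, `vax_date`,
#'   `onset_date`.
#' @seealso [vaers_assemble()]
#' @export
read_vaers_data <- function(path) {
  df <- read_vaers_csv(path, .data_cols)
  df <- drop_dup_ids(df, basename(path))
  sex <- toupper(trimws(df$SEX))
  sex[!sex %in% c("F", "M")] <- "U"
  tibble::tibble(
    report_id = trimws(df$VAERS_ID),
    receive_date = parse_vaers_date(df$RECVDATE),
    age_years = parse_nonneg(df$AGE_YRS, "AGE_YRS"),
    sex = sex,
    died = parse_flag(df$DIED),
    life_threat = parse_flag(df$L_THREAT),
    hospitalized = parse_flag(df$HOSPITAL),
    hosp_prolonged = parse_flag(df$X_STAY),
    disabled = parse_flag(df$DISABLE),
    birth_defect = parse_flag(df$BIRTH_DEFECT),
    onset_interval_days = parse_nonneg(df$NUMDAYS, "NUMDAYS"),
    vax_date = parse_vaers_date(df$VAX_DATE),
    onset_date = parse_vaers_date(df$ONSET_DATE)
  )
}

#' Read a VAERSSYMPTOMS file and unpivot to long form
#'
#' Each SYMPTOMS row carries up to five MedDRA Preferred Terms (SYMPTOM1-5);
#' reports with more than five terms continue on additional rows. The result
#' is long form, one row per (report, term) cell, blanks dropped; terms get
#' whitespace-canonicalized via [canonicalize_pt()]. Rows whose five term
#' cells are all blank are skipped with a warning.
#'
#' @param path Path to a VAERSSYMPTOMS-dialect CSV.
#' @return A tibble with columns `report_id`, `preferred_term`.
#' @export
read_vaers_symptoms <- function(path) {
  df <- read_vaers_csv(path, .symptom_cols)
  pt_cols <- paste0("SYMPTOM", 1:5)
  long <- tidyr::pivot_longer(
    df[, c("VAERS_ID", pt_cols)],
    cols = dplyr::all_of(pt_cols),
    names_to = NULL, values_to = "preferred_term"
  )
  long$preferred_term <- canonicalize_pt(long$preferred_term)
  long$report_id <- trimws(long$VAERS_ID)
  keep <- long$preferred_term != ""
  n_per_row <- tapply(keep, rep(seq_len(nrow(df)), each = length(pt_cols)), any)
  if (any(!n_per_row)) {
    warning(sprintf("%d symptom row(s) with no preferred term skipped",
                    sum(!n_per_row)), call. = FALSE)
  }
  tibble::tibble(report_id = long$report_id[keep],
                 preferred_term = long$preferred_term[keep])
}

#' Read a VAERSVAX file
#'
#' One row per (report, vaccine); co-administered vaccines keep one row each,
#' so duplicate report ids are expected here and retained.
#'
#' @param path Path to a VAERSVAX-dialect CSV.
#' @return A tibble with columns `report_id`, `vax_type`, `vax_name`.
#' @export
read_vaers_vax <- function(path) {
  df <- read_vaers_csv(path, .vax_cols)
  tibble::tibble(
    report_id = trimws(df$VAERS_ID),
    vax_type = trimws(df$VAX_TYPE),
    vax_name = trimws(df$VAX_NAME)
  )
}

#' Assemble the VAERS triplet into report and symptom tables
#'
#' Inner-joins the three parsed tables on `report_id`. A report survives only
#' if it has a DATA row, at least one Preferred Term and at least one vaccine
#' row; drops at each stage are reported via a message. (report, term) pairs
#' are de-duplicated — a term listed twice on one report counts once — and
#' term casings are unified to the first-seen spelling, case-insensitively.
#' Report-level seriousness is derived from the outcome flags with
#' [classify_serious()], and a single onset interval per report is resolved:
#' NUMDAYS when present, else `onset_date - vax_date` when both dates parse.
#'
#' @param data_tbl Tibble from [read_vaers_data()].
#' @param symptom_tbl Tibble from [read_vaers_symptoms()].
#' @param vax_tbl Tibble from [read_vaers_vax()].
#' @return A list with two tibbles:
#' \describe{
#'   \item{reports}{one row per report: the DATA fields plus `serious`,
#'     resolved `onset_interval_days`, and `vaccines` (list-column of the
#'     report's vaccine name set) and `vax_types`.}
#'   \item{symptoms}{long table of unique (`report_id`, `preferred_term`)
#'     pairs restricted to surviving reports.}
#' }
#' @export
vaers_assemble <- function(data_tbl, symptom_tbl, vax_tbl) {
  data_tbl <- data_tbl[!duplicated(data_tbl$report_id), , drop = FALSE]

  sym <- symptom_tbl
  sym$preferred_term <- unify_pt_casing(canonicalize_pt(sym$preferred_term))
  sym <- dplyr::distinct(sym, .data$report_id, .data$preferred_term)

  ids_data <- unique(data_tbl$report_id)
  ids_sym <- unique(sym$report_id)
  ids_vax <- unique(vax_tbl$report_id)
  keep_ids <- intersect(intersect(ids_data, ids_sym), ids_vax)

  n_drop_no_sym <- length(setdiff(intersect(ids_data, ids_vax), ids_sym))
  n_drop_no_data <- length(setdiff(union(ids_sym, ids_vax), ids_data))
  n_drop_no_vax <- length(setdiff(intersect(ids_data, ids_sym), ids_vax))
  if (n_drop_no_sym + n_drop_no_data + n_drop_no_vax > 0) {
    message(sprintf(
      "assemble: dropped %d report(s) without symptoms, %d without a data row, %d without a vaccine row",
      n_drop_no_sym, n_drop_no_data, n_drop_no_vax))
  }

  vax_sets <- vax_tbl[vax_tbl$report_id %in% keep_ids, , drop = FALSE]
  vax_by_id <- dplyr::summarise(
    dplyr::group_by(vax_sets, .data$report_id),
    vaccines = list(unique(.data$vax_name)),
    vax_types = list(unique(.data$vax_type)),
    .groups = "drop"
  )

  reports <- data_tbl[data_tbl$report_id %in% keep_ids, , drop = FALSE]
  reports <- dplyr::left_join(reports, vax_by_id, by = "report_id")
  reports$serious <- classify_serious(reports)

  # onset source: NUMDAYS wins; date difference fills gaps where both parse
  date_diff <- as.numeric(reports$onset_date - reports$vax_date)
  date_diff[!is.na(date_diff) & date_diff < 0] <- NA_real_
  fill <- is.na(reports$onset_interval_days) & !is.na(date_diff)
  conflict <- !is.na(reports$onset_interval_days) & !is.na(date_diff) &
    reports$onset_interval_days != date_diff
  if (any(conflict)) {
    warning(sprintf(
      "%d report(s) with NUMDAYS disagreeing with onset-vaccination date difference; keeping NUMDAYS",
      sum(conflict)), call. = FALSE)
  }
  reports$onset_interval_days[fill] <- date_diff[fill]

  symptoms <- sym[sym$report_id %in% keep_ids, , drop = FALSE]
  list(reports = tibble::as_tibble(reports),
       symptoms = tibble::as_tibble(symptoms))
}
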
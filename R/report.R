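# End-to-end pipeline: from the CSV triplet to the full table set —
# baseline strata, serious/non-serious screens, SOC distribution,
# age-stratified screens, time-to-onset tables, death-subgroup screen,
# multi-vaccine comparison and onset histogram/curve data.

#' Pipeline run configuration
#'
#' @param data_path,symptoms_path,vax_path Paths to the VAERS triplet.
#' @param cohort A [cohort_spec()] for the target vaccine.
#' @param soc_mapping_path Optional PT -> SOC mapping file; `NULL` skips the
#'   SOC table.
#' @param compare Named list of [cohort_spec()]s for the multi-vaccine
#'   comparison (the target is added automatically); `NULL` skips it.
#' @param compare_pts Preferred terms reported per vaccine in the
#'   comparison table.
#' @param top_k Rows per screen (default 10).
#' @param correction Haldane-Anscombe continuity correction for zero cells.
#' @param signal_rule `"ci"` or `"literal"`, see [compute_ror()].
#' @param out_dir Output directory for the TSV artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(data_path, symptoms_path, vax_path, cohort,
                       soc_mapping_path = NULL, compare = NULL,
                       compare_pts = c("Hypotonic-hyporesponsive episode",
                                       "Hypotonia", "Pallor", "Bronchiolitis"),
                       top_k = 10, correction = FALSE,
                       signal_rule = c("ci", "literal"),
                       out_dir = "vaersignal-output") {
  signal_rule <- match.arg(signal_rule)
  stopifnot(inherits(cohort, "cohort_spec"), top_k > 0)
  structure(list(data_path = data_path, symptoms_path = symptoms_path,
                 vax_path = vax_path, cohort = cohort,
                 soc_mapping_path = soc_mapping_path, compare = compare,
                 compare_pts = compare_pts, top_k = top_k,
                 correction = correction, signal_rule = signal_rule,
                 out_dir = out_dir),
            class = "run_config")
}

# Screen helper bound to a config's options.
screen_with <- function(config, symptoms, target_ids, comparator_ids,
                        denominator, label) {
  screen_stratum(symptoms, target_ids, comparator_ids,
                 stratum_denominator = denominator, stratum = label,
                 correction = config$correction,
                 signal_rule = config$signal_rule)
}

#' Run the full analysis pipeline
#'
#' Reads and assembles the triplet, extracts the target cohort and its
#' comparator, and writes the complete artifact set as TSV files:
#' baseline characteristics by age group, top-term screens for the serious
#' and non-serious strata and per age group, the SOC distribution of the
#' serious stratum (when a mapping is supplied), time-to-onset summaries by
#' seriousness, the death-subgroup screen, forest-plot data, onset
#' histogram and cumulative-curve data, and the multi-vaccine comparison
#' (when comparison cohorts are supplied). Any stage failure aborts the run
#' and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return Manifest tibble (`artifact`, `path`, `n_rows`), invisibly the
#'   full result list as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  fresh <- !dir.exists(out_dir)
  if (fresh) dir.create(out_dir, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  asm <- stage("assemble", {
    vaers_assemble(read_vaers_data(config$data_path),
                   read_vaers_symptoms(config$symptoms_path),
                   read_vaers_vax(config$vax_path))
  })
  reports <- asm$reports
  symptoms <- asm$symptoms

  cohort <- stage("cohort", extract_cohort(reports, config$cohort))
  comparator <- stage("comparator",
                      comparator_reports(reports, config$cohort, cohort))
  comp_ids <- comparator$report_id

  artifacts <- list()

  artifacts$baseline <- stage("baseline", baseline_table(cohort))

  serious_ids <- cohort$report_id[cohort$serious]
  nonserious_ids <- cohort$report_id[!cohort$serious]
  death_ids <- cohort$report_id[cohort$died]

  artifacts$screen_serious <- stage("screen_serious", format_screen(rank_top(
    screen_with(config, symptoms, serious_ids, comp_ids,
                length(serious_ids), "serious"), config$top_k)))
  artifacts$screen_nonserious <- stage("screen_nonserious",
                                       format_screen(rank_top(
    screen_with(config, symptoms, nonserious_ids, comp_ids,
                length(nonserious_ids), "non-serious"), config$top_k)))

  # age-stratified screens over the serious stratum
  grp <- assign_age_group(cohort$age_years)
  age_rows <- lapply(setdiff(age_group_levels, "unknown"), function(g) {
    ids <- cohort$report_id[grp == g & cohort$serious]
    if (!length(ids)) return(NULL)
    format_screen(rank_top(
      screen_with(config, symptoms, ids, comp_ids, length(ids), g),
      config$top_k))
  })
  artifacts$screen_age <- stage("screen_age", dplyr::bind_rows(age_rows))

  if (!is.null(config$soc_mapping_path)) {
    mapping <- stage("soc_mapping", load_soc_mapping(config$soc_mapping_path))
    artifacts$soc_serious <- stage("soc",
                                   soc_distribution(symptoms, serious_ids,
                                                    mapping))
  }

  # time-to-onset per top term, by seriousness
  tto_for <- function(ids, label) {
    sub <- cohort[cohort$report_id %in% ids, , drop = FALSE]
    top <- rank_top(screen_with(config, symptoms, ids, comp_ids,
                                max(length(ids), 1), label), config$top_k)
    dplyr::bind_rows(lapply(top$preferred_term, function(p) {
      onset_summary(sub, symptoms, p, label)
    }))
  }
  artifacts$tto_serious <- stage("tto", dplyr::bind_rows(
    tto_for(serious_ids, "serious"),
    tto_for(nonserious_ids, "non-serious"),
    if (length(death_ids)) tto_for(death_ids, "death")
  ))

  if (length(death_ids)) {
    artifacts$screen_death <- stage("screen_death", format_screen(rank_top(
      screen_with(config, symptoms, death_ids, comp_ids,
                  length(death_ids), "death"), 20)))
  }

  full_screen <- stage("forest", screen_with(config, symptoms,
                                             cohort$report_id, comp_ids,
                                             nrow(cohort), "all"))
  artifacts$forest <- tibble::tibble(
    preferred_term = full_screen$preferred_term,
    ror = full_screen$ror, ci_low = full_screen$ci_low,
    ci_high = full_screen$ci_high, null_line = 1
  )

  artifacts$onset_histogram <- stage("onset_histogram",
                                     onset_histogram(cohort, nrow(cohort),
                                                     "target"))
  artifacts$onset_curve <- stage("onset_curve",
                                 cumulative_curve(cohort, "target"))

  if (!is.null(config$compare)) {
    cohorts <- lapply(config$compare, function(sp) extract_cohort(reports, sp))
    cohorts <- c(stats::setNames(list(cohort), "target"), cohorts)
    artifacts$comparison <- stage("comparison",
                                  compare_vaccines(reports, symptoms, cohorts,
                                                   config$compare_pts,
                                                   correction = config$correction,
                                                   signal_rule = config$signal_rule))
  }

  manifest <- dplyr::bind_rows(lapply(names(artifacts), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(artifacts[[nm]], path, progress = FALSE)
    written <<- c(written, path)
    tibble::tibble(artifact = nm, path = path,
                   n_rows = nrow(artifacts[[nm]]))
  }))
  ok <- TRUE
  attr(manifest, "results") <- artifacts
  manifest
}

#' Compare several vaccines on mortality and selected terms
#'
#' For each cohort: total reports, death count with per-100,000 frequency,
#' and for each requested preferred term the report count, per-100,000
#' frequency and ROR against all reports outside the cohort, formatted with
#' a leading asterisk when the signal criterion is met. Terms absent from a
#' cohort are emitted with zero counts (with a warning when absent from the
#' whole dataset).
#'
#' @param reports Full assembled report table.
#' @param symptoms Long (report_id, preferred_term) table.
#' @param cohorts Named list of report tibbles, one per vaccine (>= 2).
#' @param pts Preferred terms to compare.
#' @param ... Passed to [compute_ror()].
#' @return Tibble with one row per (vaccine, term) plus death rows:
#'   `vaccine`, `n_reports`, `measure` ("death" or the term), `count`,
#'   `frequency_per_100k`, `ror_ci` (NA for death rows).
#' @export
compare_vaccines <- function(reports, symptoms, cohorts, pts, ...) {
  if (length(cohorts) < 2) stop("need at least two cohorts", call. = FALSE)
  known <- tolower(unique(symptoms$preferred_term))
  for (p in pts) {
    if (!tolower(canonicalize_pt(p)) %in% known) {
      warning("preferred term not present in data: ", p, call. = FALSE)
    }
  }
  rows <- lapply(names(cohorts), function(v) {
    coh <- cohorts[[v]]
    n <- nrow(coh)
    other_ids <- setdiff(reports$report_id, coh$report_id)
    death_row <- tibble::tibble(
      vaccine = v, n_reports = n, measure = "death",
      count = sum(coh$died),
      frequency_per_100k = if (n > 0) normalized_frequency(sum(coh$died), n)
                           else NA_integer_,
      ror_ci = NA_character_
    )
    pt_rows <- dplyr::bind_rows(lapply(pts, function(p) {
      ct <- build_contingency(symptoms, coh$report_id, other_ids, p)
      res <- compute_ror(ct$a, ct$b, ct$c, ct$d, ...)
      fmt <- function(x) formatC(round_half_up(x, 2), format = "f",
                                 digits = 2)
      ror_ci <- if (res$undefined) {
        NA_character_
      } else {
        paste0(if (isTRUE(res$is_signal)) "*" else "",
               fmt(res$ror), " (", fmt(res$ci_low), " - ",
               fmt(res$ci_high), ")")
      }
      tibble::tibble(
        vaccine = v, n_reports = n, measure = p, count = ct$a,
        frequency_per_100k = if (n > 0) normalized_frequency(ct$a, n)
                             else NA_integer_,
        ror_ci = ror_ci
      )
    }))
    dplyr::bind_rows(death_row, pt_rows)
  })
  dplyr::bind_rows(rows)
}
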
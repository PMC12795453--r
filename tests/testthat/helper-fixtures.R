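# In-code fixtures: tiny handwritten VAERS-dialect CSVs and a small seeded
# synthetic triplet shared across test files.

write_lines_tmp <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# A 4-report handwritten triplet: r1 infant death, r2 non-serious infant,
# r3 adult (no symptoms -> dropped on assembly), r4 comparator-vaccine child.
tiny_data_lines <- c(
  "VAERS_ID,RECVDATE,AGE_YRS,SEX,DIED,L_THREAT,HOSPITAL,X_STAY,DISABLE,BIRTH_DEFECT,NUMDAYS,VAX_DATE,ONSET_DATE",
  "r1,01/15/2012,0.25,F,Y,,,,,,0,01/10/2012,01/10/2012",
  "r2,03/02/2015,0.5,M,,,,,,,1,02/20/2015,02/21/2015",
  "r3,06/30/2020,42,F,,,Y,,,,,06/01/2020,06/03/2020",
  "r4,08/10/2018,3,U,,,,,,,33,08/01/2018,09/03/2018"
)
tiny_symptom_lines <- c(
  paste0("VAERS_ID,SYMPTOM1,SYMPTOMVERSION1,SYMPTOM2,SYMPTOMVERSION2,",
         "SYMPTOM3,SYMPTOMVERSION3,SYMPTOM4,SYMPTOMVERSION4,SYMPTOM5,",
         "SYMPTOMVERSION5"),
  "r1,Pyrexia,27.0,Crying,27.0,,,,,,",
  "r2,pyrexia ,27.0,,,,,,,,",
  "r4,Gait disturbance,27.0,Pyrexia,27.0,,,,,,"
)
tiny_vax_lines <- c(
  "VAERS_ID,VAX_TYPE,VAX_NAME",
  "r1,PNC10,SYNFLORIX",
  "r2,PNC10,SYNFLORIX",
  "r3,PNC10,SYNFLORIX",
  "r4,PNC13,PREVNAR13"
)

tiny_triplet <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  paths <- c(data = file.path(dir, "data.csv"),
             symptoms = file.path(dir, "symptoms.csv"),
             vax = file.path(dir, "vax.csv"))
  writeLines(tiny_data_lines, paths["data"])
  writeLines(tiny_symptom_lines, paths["symptoms"])
  writeLines(tiny_vax_lines, paths["vax"])
  paths
}

tiny_assembled <- function(env = parent.frame()) {
  paths <- tiny_triplet(env)
  suppressMessages(vaers_assemble(read_vaers_data(paths["data"]),
                                  read_vaers_symptoms(paths["symptoms"]),
                                  read_vaers_vax(paths["vax"])))
}

# Small seeded synthetic triplet, assembled; cached per session.
small_config <- function(seed = 11L, n_target = 400L, n_comp = 1200L) {
  generator_config(
    seed = seed,
    vaccines = list(
      SYNFLORIX = list(n_reports = n_target, vax_type = "PNC10",
                       vax_name = "SYNFLORIX"),
      COMPARATOR = list(n_reports = n_comp, vax_type = "PNC13",
                        vax_name = "PREVNAR13")
    )
  )
}

.small_cache <- new.env(parent = emptyenv())
small_assembled <- function() {
  if (is.null(.small_cache$asm)) {
    gen <- generate_vaers(small_config())
    dir <- file.path(tempdir(), "vaersignal-small-fixture")
    paths <- write_fixture(gen, dir)
    .small_cache$gen <- gen
    .small_cache$asm <- suppressMessages(suppressWarnings(
      vaers_assemble(read_vaers_data(paths["data"]),
                     read_vaers_symptoms(paths["symptoms"]),
                     read_vaers_vax(paths["vax"]))))
  }
  list(gen = .small_cache$gen, asm = .small_cache$asm)
}

# Run the full pipeline on the shared small fixture.
run_small_pipeline <- function(out_dir, top_k = 10) {
  gen <- generate_vaers(small_config())
  dir <- file.path(tempdir(), "vaersignal-pipe-fixture")
  paths <- write_fixture(gen, dir)
  cfg <- run_config(
    data_path = paths[["data"]], symptoms_path = paths[["symptoms"]],
    vax_path = paths[["vax"]],
    cohort = cohort_spec("SYNFLORIX"),
    soc_mapping_path = system.file("extdata", "synthetic_pt_soc_mapping.tsv",
                                   package = "vaersignal"),
    compare = list(PREVNAR13 = cohort_spec("PREVNAR13")),
    top_k = top_k, out_dir = out_dir
  )
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
}

# Minimal report tibble for cohort/temporal unit tests.
make_reports <- function(n, age = NA_real_, sex = "U", serious = FALSE,
                         died = FALSE, onset = NA_real_) {
  tibble::tibble(
    report_id = sprintf("s%03d", seq_len(n)),
    receive_date = as.Date("2015-06-01"),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    died = rep_len(died, n),
    life_threat = FALSE, hospitalized = FALSE, hosp_prolonged = FALSE,
    disabled = FALSE, birth_defect = FALSE,
    onset_interval_days = rep_len(onset, n),
    serious = rep_len(serious, n) | rep_len(died, n),
    vaccines = rep(list("SYNFLORIX"), n),
    vax_types = rep(list("PNC10"), n)
  )
}
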
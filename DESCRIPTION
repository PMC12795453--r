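Package: vaersignal
Title: Disproportionality Signal Detection for VAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event report
    databases distributed in the VAERS CSV dialect (DATA / SYMPTOMS / VAX file
    triplets keyed by report id). Reads, validates and de-duplicates the
    triplets into a report-level table and a long report-by-preferred-term
    table; classifies report seriousness from the structured outcome flags;
    builds per-term 2x2 contingency tables against a comparator universe and
    computes reporting odds ratios with Wald 95% confidence intervals, signal
    flags and per-100,000 normalized reporting frequencies; summarizes
    time-to-onset by term and stratum with binned histograms and cumulative
    onset curves; aggregates preferred terms to System Organ Class
    distributions; and compares multiple vaccines side by side. A seeded
    synthetic-data generator emits VAERS-format fixtures with known ground
    truth (embedded reporting-rate ratios, seriousness and missingness rates)
    so every stage is testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
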
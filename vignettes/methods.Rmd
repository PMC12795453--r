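---
title: "Methods: reporting odds ratio screening of VAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporting odds ratio screening of VAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vaersignal` screens spontaneous adverse-event report databases in the
VAERS CSV dialect for disproportionate reporting. This vignette documents
the statistical model, the data-handling contracts, the synthetic-data
generator that stands in for the live database, and the numerical and
design choices a maintainer should know about.

## The disproportionality model

Spontaneous-report systems have no exposure denominator, so the analysis
compares the *composition* of reports rather than incidence. For a target
vaccine and one MedDRA Preferred Term (PT), reports are cross-classified
into the 2×2 table (a, b, c, d) — target reports with and without the PT,
comparator reports with and without it — and screened with the reporting
odds ratio:

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},$$

with the Wald interval $\exp(\ln \mathrm{ROR} \pm 1.96\,\mathrm{SE})$ and
the signal rule *lower 95% bound > 1*. The multiplier is the literal 1.96
of the published formula rather than `qnorm(0.975)`; the difference is in
the fifth decimal but matters when results must re-derive exactly.

Assumptions worth keeping in view:

* Cells are **report counts** with PTs de-duplicated per report. A PT
  listed on two continuation rows of one report contributes once.
* The Wald interval is asymptotic; with any expected cell below ~5 its
  coverage degrades. The test suite measures coverage at moderate cell
  sizes (≈95% over 2,000 null replicates) — that result does not transfer
  to strata with single-digit counts, which is why small-age-stratum
  intervals should be read qualitatively.
* No multiple-testing adjustment is applied: a screen over hundreds of PTs
  at the 95% level will flag ~5% of null PTs. This matches standard
  pharmacovigilance practice, where the ROR screen is hypothesis
  *generating*; it is stated here as a limitation.
* Disproportionality is not risk. A high ROR reflects reporting behavior
  as much as biology; nothing here supports causal interpretation.

Two documented variants exist. `signal_rule = "literal"` implements the
arithmetic reading `ROR − 1.96·SE > 1` that occasionally appears in print;
it is inconsistent with the log-scale CI and kept only for comparison.
`correction = TRUE` applies the Haldane–Anscombe +0.5 to all four cells of
zero-cell tables; the default instead marks such tables `undefined` and
excludes them from signal lists, since a zero cell usually means the PT is
simply absent from one universe.

### Comparator universe

The default comparator is *all other reports in the supplied files* — the
"other drugs" row of the classical 2×2. For multi-vaccine comparison
tables each vaccine's ROR is computed the same way (cohort vs everything
outside it). A named-vaccine comparator set is available through
`cohort_spec(comparator = ...)` when a restricted universe (e.g. only
same-class vaccines) is wanted; the choice changes c and d and therefore
every ROR, so outputs should state it.

## Normalized frequency and rounding

Cross-vaccine comparability uses
`round_half_up(a / n × 100 000)` per PT, where `n` is the stratum size.
Subgroup tables (serious only, one age group) use the subgroup size as
denominator. All printed percentages round half *up* (one decimal for
stratum percentages, two for SOC percentages); base R's banker's rounding
would make published-style values fail to re-derive from their counts,
which is why the package carries its own `round_half_up()`.

## Data-handling contracts

* **Seriousness** is the disjunction of the six structured outcome flags
  (death, life-threatening, hospitalization, prolonged hospitalization,
  disability, congenital anomaly). The regulation's "medically important"
  clause requires narrative review and cannot be derived from structured
  fields; emergency-room visits are not a criterion. Death implies
  serious by construction.
* **Age groups** are [0,2), [2,11), [11,19), [19,55), [55,∞) plus
  "unknown"; the edges are chosen so that each published per-group age
  range (e.g. infant maximum 1.60 years, child maximum 8.00) falls in one
  bin. The bins partition the axis, so group counts always sum to the
  cohort (the overall stratum additionally includes age-unknown reports).
* **PT canonicalization**: trim, collapse internal whitespace, then unify
  case-insensitive duplicates to the first-seen casing. VAERS archives mix
  casings across years; exact-string matching would split one PT into
  several.
* **De-duplication**: duplicate report ids within a file keep the first
  row (warned). Reports lacking a DATA row, a vaccine row, or any PT are
  dropped with logged counts — the report universe is "reports *with*
  AEs" by construction.
* **Onset interval**: the NUMDAYS field wins; when it is blank and both
  vaccination and onset dates parse, their difference fills in. A
  disagreement between the two sources keeps NUMDAYS and warns. Negative
  values are invalid and become missing.
* **Encoding**: UTF-8 first, Latin-1 fallback, since the archives mix
  both.

## Time-to-onset

Quartiles use linear interpolation between order statistics
(`stats::quantile()` type 7). The method is stated because published
onset tables rarely say which quantile definition they use and the choices
differ at small n. The mean is always reported beside the median: onset
distributions are extremely right-skewed (most events on day 0–1, a tail
out to years), so the two diverge by design, not by error. Histogram bins
are the conventional 0–30, 31–90, 91–180, 181–360, >360 days, closed on
both ends on integer days (day 30 → first bin, day 31 → second).

## System Organ Class aggregation

MedDRA is licensed, so the PT→SOC mapping is user-supplied; a synthetic
41-term mapping covering the common pediatric-vaccine PTs ships in
`inst/extdata/synthetic_pt_soc_mapping.tsv` for offline tests. The
counting unit is PT *occurrences* ((report, PT) pairs), not reports — one
report feeds every SOC its terms map to, so SOC totals exceed the report
count. Unmapped PTs pool into an "Unmapped" row outside the percentage
denominator.

## The synthetic generator

`generate_vaers()` emits the three-file dialect with known ground truth.
Its defaults describe a mid-sized pediatric-vaccine report population:

| parameter | default | rationale |
|---|---|---|
| target cohort size | 1,704 reports | a realistic 15-year accumulation for a non-US-market pediatric vaccine |
| comparator size | 10,000 reports | large enough that comparator noise does not dominate target CIs |
| serious share | 0.49 | pediatric-vaccine report mixes run near half serious |
| sex split F/M/U | 0.346 / 0.400 / 0.254 | quarter-missing sex is typical of international reports |
| age mixture | expected 1054 / 22 / 0 / 13 / 19 per group, 596 age-unknown | infant-dominated, with deliberately sparse adult strata (n≈13–19) so age-stratified code meets realistic sparsity; the 11–18 bin is intentionally empty by default |
| onset model | π₀ = 0.7 point mass on {0, 1} (0.75/0.25 within), else 2 + Geometric(mean ≈ 28) | puts the median at 0 while the tail drags the mean to ≈9 days — the mean ≫ median signature |
| onset missing | 0.178 | typical NUMDAYS missingness |
| PTs per report | (0.45, 0.30, 0.15, 0.07, 0.03) on 1…5 | the five-slot file layout; extra terms spill onto continuation rows |

Background PTs are drawn per report (K terms, weighted without replacement
from an age-group-specific catalog: systemic terms for infants,
injection-site terms for adults). **Signal PTs** — by default a
hypotonic-hyporesponsive-episode-like quartet at target rates 17.7%, 8.5%,
9.2%, 4.2% against comparator rates of 1.0%, 2.6%, 3.1%, 0.18% — are
assigned by *independent per-report Bernoulli draws* and are excluded from
the background catalog. That separation is what makes the ground truth
exact: the generating ROR of a signal PT is the closed-form odds ratio of
its two Bernoulli probabilities, stored in the truth record, and the
per-cohort count is exactly Binomial(n, p). The replicated
parameter-recovery checks therefore simulate the binomial law directly
(500 replicates at n = 2,000 per cohort for ratios 2, 5 and 20), with a
smaller set of 25 full file→assembly→screen replicates confirming that the
whole pipeline preserves the same coverage.

What the generator does **not** emulate: narrative text, reporter
stochastic duplication (the same patient reported twice under different
ids), secular reporting trends, correlated PT co-occurrence beyond the
age-group catalogs, MedDRA version drift, and seriousness-dependent PT
profiles (the serious and non-serious strata share one catalog). Passing
tests demonstrate that the *computations* are correct under a controlled
model — they do not validate conclusions about any real vaccine.

## Problem sizes and determinism

The test suite runs the full default population (11,704 reports) once for
calibration checks, a 20,000-report run for marginal convergence (3σ
binomial bands), and shared 1,600-report fixtures elsewhere; the ROR
implementation is verified against an exhaustive recount-and-odds-ratio
oracle on all 1,296 tables with cells in 1…6 at 10⁻¹² relative tolerance.
All randomness flows from explicit integer seeds: the same seed yields
byte-identical fixture files and pipeline artifacts, which the suite
asserts by comparing file contents across reruns.

## Known limitations

* Wald intervals at single-digit cell counts are unreliable; published
  subgroup tables with such counts inherit the problem.
* The "medically important" seriousness clause is not implemented
  (structured fields cannot express it), so seriousness here may slightly
  undercount a narrative-reviewed classification.
* Cross-file de-duplication (domestic vs non-domestic archives) keeps the
  first record by receive date; record linkage beyond exact id equality is
  out of scope.
* ROR is the only statistic implemented; PRR, IC/BCPNN and EBGM shrinkage
  methods are deliberate non-goals.
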
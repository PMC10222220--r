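---
title: "Methods: disproportionality screening of Kampo crude drugs for DILI"
author: "KampoSignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of Kampo crude drugs for DILI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KampoSignal)
```

## The problem

Kampo medicines are fixed combinations of crude drugs (herbal or mineral
ingredients), so a spontaneous report naming a Kampo product carries no
direct information about which ingredient drove the adverse event. This
package screens all crude drugs at once for association with drug-induced
liver injury (DILI) in a spontaneous-reporting database distributed in the
JADER layout: a DRUG table (case id, drug name, involvement category), a
REAC table (case id, MedDRA preferred term) and a DEMO table (case id, sex,
age decade, reporting year).

The pipeline has five stages.

1. **Dataset construction.** DRUG and REAC are deduplicated on their exact
   key tuples, restricted to *suspected* drugs, and inner-joined with DEMO on
   the case id into the *report-based dataset* (one row per case x suspected
   drug x preferred term; demographics broadcast). Collapsing to one row per
   case — with every flag OR-ed over the case's reports ("priority to
   applicable") and cases with missing sex or age excluded — gives the
   *patient-based dataset*, held as a `PatientCohort` (a
   `SummarizedExperiment` whose `exposure` assay is the binary crude-drug x
   patient matrix).
2. **Flagging.** The DILI flag marks any report whose preferred term is in a
   configurable term list (a flat export of the hepatic SMQ families; the
   package ships a reduced stand-in, the full-scale list has 228 terms).
   Drug names that resolve — directly or through an alias table — to a Kampo
   medicine set the Kampo flag and the crude-drug flags of the medicine's
   composition row.
3. **Collinearity grouping.** Crude drugs that always co-occur (fixed
   compositions, co-prescription) produce nearly identical indicator columns.
   All pairwise Spearman correlations are computed — for 0/1 vectors Spearman
   rho equals the Pearson (phi) coefficient, which is how it is evaluated —
   and indicators with rho > 0.9 are merged transitively (connected
   components). The member with the strongest outcome correlation represents
   the group; labels join members with `>` (strictly ordered) or `=` (tied).
   On the full-scale data this yields 104 groups from 126 crude drugs.
4. **Signal statistics.** For each group a 2x2 table of exposure against the
   DILI flag is built over patients. The reporting odds ratio is computed
   with the Haldane-Anscombe 1/2 correction,
   $ROR = \frac{(a+\frac12)(d+\frac12)}{(b+\frac12)(c+\frac12)}$, with a Wald
   95% CI on the log scale using the corrected cells. Fisher's exact test
   (two-sided) is evaluated on the **raw** integer counts. A group is a
   *signal* iff ROR > 1, p < 0.05 and the report count a+b is at least 10.
5. **Volcano plot.** Each group is drawn at (ln ROR, −log10 p), coloured by
   log10 report count clipped to the fixed range 0–3.5, with a dashed line
   at p = 0.05.

## Design choices where the procedure was open

* **Correction scope.** The 1/2 correction is described as applied "to all
  cells", but an exact test on non-integer counts is undefined. We read the
  correction as applying to the ROR and its CI only and keep Fisher's test
  on raw counts; `signalTest(..., debugRawCI = TRUE)` additionally reports
  the uncorrected ROR/CI so both readings can be compared.
* **CI formula.** No interval formula is fixed by the procedure; we use the
  Wald interval on the log scale with corrected cells — the standard choice
  in disproportionality analysis — with the exact normal quantile
  `qnorm(0.975)` rather than the rounded 1.96.
* **Two-sided test.** Sidedness is not specified; we use the conventional
  two-sided minimum-likelihood rule (the `stats::fisher.test` convention,
  with the same 1 + 1e-7 floating-point guard). The signal criterion
  already enforces directionality through ROR > 1. The test is implemented
  by direct hypergeometric enumeration so that tens of thousands of tables
  (null-calibration replicates) can be screened quickly; agreement with
  `stats::fisher.test` to 1e-10 is asserted in the test suite over every
  2x2 table with n <= 50.
* **Transitive merging.** "Integrated with each other" does not say whether
  merging is transitive; we use connected components, which yields a
  well-defined partition (near-1 correlations are near-transitive in
  practice). The strict inequality rho > 0.9 is kept.
* **Group indicator.** A group's patient-level flag is the OR of its
  members (any member usage counts), not the representative's own column;
  at rho > 0.9 the difference is negligible and OR is the conservative
  superset. Both modes exist behind `groupFlags(..., mode =)`.
* **Representative ties.** Exact ties in outcome correlation are broken
  lexicographically and printed with `=`, so output is deterministic.
* **Deduplication.** The published cleaning procedure for JADER is cited
  without detail; the reproducible default is exact-tuple deduplication on
  (case, drug, involvement) / (case, term), keeping the first occurrence.
  An opt-in `case-version` mode keeps each case's highest report version
  first when a version column is present.
* **Missing values and encodings.** Empty strings and a configurable
  missing vocabulary map to missing; age decades are parsed from both
  `"20s"` and `"20歳代"` forms; string comparison uses NFKC (compatibility)
  normalization plus case folding, because JADER strings vary in character
  width — plain canonical normalization would not fold width variants.
  Real distributions are CP932-encoded with Japanese headers: pass
  `encoding = "CP932"` and a YAML column map.
* **Numerical floors.** For the volcano y axis only, p is floored at 1e-300
  before −log10; reported p values are untouched. All-zero or one-margin
  tables get p = 1 and, after correction, ROR = 1 with a finite CI.

## The synthetic generator and what it does (not) show

`simulateJaderTables()` emits DRUG/REAC/DEMO CSVs plus a `truth.json` with
the planted ground truth; `simulateCohort()` is the matrix-level fast path
producing the post-ETL `PatientCohort` from the same draws. Each case gets
demographics (sex 51.1/48.9, age mass at the 60s/70s decades, years
2004–2021 — the full-scale marginals), at most one Kampo medicine, crude-drug
exposures through the composition matrix, co-prescribed collinear clusters
(forcing rho = 1), filler drugs and events, injected exact duplicates, and a
DILI outcome from the logistic model

$$\mathrm{logit}\,P(\mathrm{DILI}) = \mathrm{logit}(p_0) +
\textstyle\sum_{\text{exposed } c} \ln OR_c .$$

Defaults are fixed once as the desk-scale study conditions: n = 20,000
patients, baseline DILI probability 0.08 (the full-scale patient-level DILI
prevalence), duplicate rate 0.02, missing-demographics rate 0.03. Kampo
usage is 0.15 rather than the full-scale 0.9%: the desk cohort is about
thirty times smaller than the full database, and at 0.9% every crude-drug
2x2 table would hold single-digit exposed counts — below the pipeline's own
>= 10-report filter — so prevalence is scaled to keep absolute exposed
counts in the range the full-scale tables actually have.

`simulateIndependentExposures()` is the statistical calibration harness:
independent Bernoulli exposure indicators with the same outcome model and no
composition structure. Two of its operating characteristics matter and are
documented here because they shape the validation suite:

* **Marginal vs conditional odds ratios.** The ROR is a *marginal* 2x2
  collapse, the planted effect a *conditional* logistic coefficient. With a
  rare outcome and sparse planting the two coincide; with many simultaneous
  planted effects the marginal ROR is systematically attenuated
  (non-collapsibility plus contamination of the reference rows by the other
  planted exposures). At n = 20,000, baseline 0.08 and ten planted OR-5
  drugs at 2% prevalence, the expected marginal ROR is about 4.2, not 5 —
  for any exposure prevalence the attenuation-versus-variance tradeoff keeps
  |ln ROR − ln 5| < 0.3 from being a reliable per-group bound. The
  validation suite therefore checks the three-part signal criterion (and the
  >= 95% null-group rejection) on the ten-planted configuration, and the
  0.3 log-accuracy bound in the sparse regime (a single planted drug), where
  the identity holds.
* **Exact-test discreteness.** Fisher's test is conservative; its size
  approaches 0.05 from below as the cell counts grow. The null-calibration
  configuration (104 independent indicators, 200 replicates, n = 20,000)
  uses exposure prevalence 0.15 so the smallest expected cell is ~240, where
  the exact size is ~0.048 — inside the binomial 99% band around 0.05 that
  the suite asserts. At rare-exposure settings the same check would fail
  for the test's intrinsic conservatism, not for an implementation error.

The generator emulates the *structure* of spontaneous-reporting data
(multi-drug cases, duplicate rows, missing demographics, composition-induced
collinearity, a planted outcome model). It does not model reporting bias,
temporal trends, dose, or real drug-name vocabularies beyond a small alias
file — so green tests certify the pipeline's arithmetic and recovery
behaviour, not epidemiological validity on real JADER. Note also that with
a single planted crude drug the end-to-end run typically flags *several*
groups: crude drugs sharing medicines with the planted one are genuinely
marginally associated (the pseudo-correlation phenomenon that motivates
cautious interpretation of disproportionality results).

## Problem sizes in the validation suite

Oracle equivalence of ROR/CI/Fisher is asserted over all 316,251 tables with
n <= 50; partition recovery, null calibration (200 replicates) and planted
recovery run at n = 20,000 with fixed seeds; the full CSV round trip runs at
n in the low thousands. The whole suite completes in roughly two minutes on
one CPU.

## Limitations

* Desk-scale runs cannot reproduce the full-scale published RORs (e.g.
  Scutellaria Root 8.63, CI 7.97–9.35); those require the complete PMDA
  extract, which users must download themselves. The packaged reference
  tabulations cover only the printed marginals used for arithmetic checks.
* The shipped composition matrix, DILI term list and alias table are reduced
  synthetic stand-ins; real analyses must supply curated files (the
  manufacturer-priority rules that produce a composition file are data
  provenance, not computation).
* No multiple-testing correction is applied — by design the report-count
  filter plays that role; PRR/IC/EBGM and regression-based confounding
  control are out of scope.

## A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(nPatients = 20000, seed = 1,
                        plantedEffects = c("Scutellaria Root" = 5))
paths <- simulateJaderTables(cfg, "sim")
run <- runPipeline(paths["drug"], paths["reac"], paths["demo"], "out")
head(as.data.frame(run$results[order(-run$results$ror), ]))
plotVolcano(run$results)
```
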
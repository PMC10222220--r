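# KampoSignal

Pharmacovigilance signal detection for the crude drugs contained in Kampo
medicines, against drug-induced liver injury (DILI), from a
spontaneous-reporting database in the JADER layout (the PMDA's Japanese
Adverse Drug Event Report distribution: DRUG / REAC / DEMO CSV tables keyed
by case id). It is written for pharmacoepidemiologists and
pharmacovigilance analysts who want the full pipeline — dataset
construction, flagging, collinearity grouping, disproportionality
statistics, volcano plot — reproducible from the raw tables, and testable
end to end without the (non-redistributable) PMDA download through a
bundled synthetic generator with planted ground truth.

## The statistic

Each crude-drug *group* g is tabulated against the DILI flag over patients:

|            | DILI | no DILI |
|------------|------|---------|
| exposed    | a    | b       |
| unexposed  | c    | d       |

and screened with the Haldane–Anscombe corrected reporting odds ratio and a
Wald 95% CI on the log scale,

    ROR = ((a+1/2)(d+1/2)) / ((b+1/2)(c+1/2))
    CI  = exp( ln ROR ± z_0.975 · sqrt( Σ_cell 1/(cell+1/2) ) )

plus a two-sided Fisher exact p value on the raw counts. A group is a
**signal** iff `ROR > 1`, `p < 0.05` and the report count `a+b ≥ 10`.
Upstream of this, crude-drug indicators with pairwise Spearman ρ > 0.9
(equal to the phi coefficient for binary flags) are merged into groups by
connected components, labelled `A > B = C` in descending correlation with
the outcome; downstream, every group is drawn on a volcano plot at
(ln ROR, −log10 p), coloured by log10 report count clipped to 0–3.5.

## Worked example

Simulate a 20,000-case JADER-shaped database in which Scutellaria Root
carries a planted odds ratio of 5 on DILI, then run the whole pipeline:

```r
library(KampoSignal)
cfg <- simulationConfig(nPatients = 20000, seed = 1,
                        plantedEffects = c("Scutellaria Root" = 5))
paths <- simulateJaderTables(cfg, "sim")
run <- runPipeline(paths["drug"], paths["reac"], paths["demo"], "out")

run$cohort
#> PatientCohort: 15968 cases x 51 crude-drug indicators
#>   DILI flagged: 1428  Kampo users: 2885
#>   cases excluded for missing sex/age: 482
run$groups
#> CrudeDrugGroups: 51 crude drugs in 45 groups (rho > 0.9)
#>   merged: Donkey-hide Glue = Talc | Fossil Bone = Oyster Shell | ...

res <- run$results
head(as.data.frame(res[order(-res$ror), ]))
#>                                         label   a   b  ror ci_low ci_high  p_value n_reports is_signal
#> 1                  Fossil Bone = Oyster Shell  37  60 6.45   4.28    9.73 4.25e-15        97      TRUE
#> 2                             Forsythia Fruit  36  67 5.62   3.74    8.44 2.27e-13       103      TRUE
#> 3 Glehnia Root and Rhizome = Ophiopogon Tuber  34  66 5.38   3.56    8.15 2.59e-12       100      TRUE
#> 4                            Scutellaria Root 205 476 4.96   4.17    5.90 3.29e-59       681      TRUE
#> 5                              Coptis Rhizome  47 137 3.60   2.58    5.03 2.32e-11       184      TRUE
#> 6                             Platycodon Root  75 228 3.49   2.68    4.56 1.61e-16       303      TRUE
plotVolcano(res)
```

Reading the output: 2,885 of 15,968 retained cases used a Kampo medicine
(cases with missing sex/age were dropped, as the construction requires);
identical exposure columns merged (e.g. `Fossil Bone = Oyster Shell`, two
drugs that only co-occur). The planted Scutellaria Root group is recovered
with ROR 4.96 (CI 4.17–5.90) on 681 reports — a clear signal. Note the
groups *above* it: Fossil Bone = Oyster Shell occurs only inside a medicine
that also contains Scutellaria Root, so it inherits a strong marginal
association from composition alone. That pseudo-correlation is intrinsic to
disproportionality screening of fixed-composition medicines and is why
signals flag associations, not causes.

To analyse a real JADER extract, point `runPipeline()` at the downloaded
CSVs with `encoding = "CP932"`, a YAML column map for the Japanese headers,
and curated composition / DILI-term / alias files in place of the reduced
stand-ins shipped under `inst/extdata/`.

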
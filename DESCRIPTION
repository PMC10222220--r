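Package: KampoSignal
Title: Disproportionality Signal Detection for Crude Drugs in Kampo Medicines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pharmacovigilance pipeline for spontaneous-reporting
    databases in the JADER (Japanese Adverse Drug Event Report) layout.
    Builds report-based and patient-based datasets from DRUG/REAC/DEMO
    tables, flags drug-induced liver injury (DILI) events from a MedDRA
    preferred-term list, maps Kampo medicines to their constituent crude
    drugs through a composition matrix, merges collinear crude-drug
    indicators into groups by Spearman correlation, and screens each group
    for DILI association with the Haldane-Anscombe corrected reporting odds
    ratio, Wald 95% confidence interval, Fisher's exact test and a minimum
    report-count filter, with volcano-plot output. Includes a synthetic
    JADER-shaped data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    stringi,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Pharmacogenomics, Epidemiology
RoxygenNote: 7.3.3
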
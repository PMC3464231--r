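Package: ing4nfkb
Title: ING4/NF-kB Gene-Signature Scoring and Survival Stratification in
    Breast Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the ING4/NF-kB axis in breast tumors:
    delta-delta-Ct qPCR fold-change analysis and the induced/repressed
    filter cascade that derives NF-kB-target gene signatures; tissue
    microarray immunohistochemistry punch-score aggregation, low/high
    dichotomization and exact contingency testing; a median-vote gene
    signature score; receiver-operating-characteristic cutoff selection,
    Kaplan-Meier estimation, log-rank testing and hazard-ratio estimation
    implemented from first principles; and seeded synthetic-cohort
    generators with known ground truth for end-to-end validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    optparse,
    yaml
biocViews: GeneExpression, Survival, ImmunoOncology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
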
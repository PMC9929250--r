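Package: multiprot
Title: Multilevel Proteomic Subtyping and Differential Analysis for Paired Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multilevel (proteome, phospho-proteome,
    transcription-factor activity) analysis of paired tumor/normal cancer cohorts:
    fraction-of-total (FOT) and quantile normalization with sample-level quality
    control, paired and unpaired rank-based differential screens with
    Benjamini-Hochberg correction, kinase-substrate enrichment analysis (KSEA)
    z-scores with a permutation null, TFRE-style transcription-factor enrichment
    and master-TF nomination, Monti consensus-clustering subtype discovery with
    CDF/delta-area k selection, a Bayes-rule linear-predictor-score subtype
    classifier, single-sample signature scoring (ssGSEA) with immune/stroma
    aggregates and the Th1/Th2 indicator, cell-cycle module scoring and phase
    assignment, mutation cis/trans-effect testing, and survival statistics
    (Kaplan-Meier, log-rank, Cox, optimal cutpoint). A synthetic cohort generator
    with a ground-truth ledger makes every stage verifiable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
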
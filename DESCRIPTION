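Package: mecfsomics
Title: Multi-Layer PBMC Bioenergetic, Proteomic and Metabolomic Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the multi-layer analysis of small case-control cohorts
    profiled by PBMC extracellular-flux assays, TMT quantitative proteomics,
    targeted plasma metabolomics and clinical questionnaires, as used in
    exploratory ME/CFS studies. Computes a 14-parameter bioenergetic profile
    (coupling efficiency, proton leak, spare respiratory capacity, glycolytic
    parameters) from raw OCR/ECAR traces; screens protein tables for
    differentially altered proteins with control-CV-derived fold-change
    thresholds; preprocesses targeted-metabolomics panels (QC filter, minimum/5
    imputation, generalised-log transform, Pareto scaling) and runs
    fold-change, t-test/FDR and PCA screens; and correlates questionnaire
    scores (FSMC, SF-36, COMPASS-31) with bioenergetics. A seeded
    synthetic-cohort generator emulates all four data layers so every stage is
    testable offline, with ground truth for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
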
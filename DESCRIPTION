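Package: vkmet
Title: Serum and Urine Metabolomics Coupled with Network Pharmacology for
    Vinegar-Processed Kansui
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible implementation of an LC-MS
    metabolomics marker-discovery workflow coupled with network
    pharmacology, motivated by studies of vinegar-processed kansui
    (Euphorbia kansui) in rat models of malignant ascites. Provides
    feature-table preprocessing (missing-value imputation, QC relative
    standard deviation filtering, Pareto scaling), from-scratch PCA and
    OPLS-DA with R2X/R2Y/Q2, permutation validation, S-plots and VIP
    scores, differential-marker screening (VIP and Welch t-test),
    exact-mass adduct annotation with ppm tolerance, pathway
    over-representation and topology impact analysis, and
    compound-target-metabolite network assembly with centrality-based
    target ranking. Includes a seeded synthetic-data generator emulating
    the four-group study design, and the published compound, metabolite
    and target tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
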
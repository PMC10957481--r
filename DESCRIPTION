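Package: tcelldyn
Title: Longitudinal T Cell Repertoire Dynamics and Translational Trial
    Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for the translational and outcome analyses used in
    biomarker-directed immunotherapy trials: parsing and filtering of
    T cell receptor beta clonotype tables (AIRR Rearrangement and
    immunoSEQ-style dialects), repertoire summary statistics (Shannon
    entropy, Pielou evenness, clonality, Morisita-Horn overlap),
    per-clonotype Fisher exact expansion testing with Benjamini-Hochberg
    false-discovery control and the newly-detected-expanded rule,
    single-sample gene-set enrichment (ssGSEA) scoring of tumor
    inflammation signatures with subgroup rank-sum comparisons and
    NanoString-style panel normalization, RECIST-derived response and
    survival endpoints with protocol missed-visit censoring and
    Kaplan-Meier estimation, and seeded simulators for all three input
    classes with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    fgsea,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
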
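Package: pmiscreen
Title: Bone Proteome Biomarker Screening for Late Postmortem Interval Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating late postmortem interval (PMI) classes from
    label-free quantification (LFQ) bone proteome abundance tables. Builds
    per-condition consistent proteomes and representative protein sets with
    UpSet-style intersection summaries, computes in-silico biochemical profiles
    (molecular weight, acidic and basic residue composition) from protein
    sequences, performs unsupervised ordination (standardized PCA with K-means
    on components, multiple correspondence analysis of presence/absence), and
    runs a resampling-stabilized random-forest protocol with Mean-Decrease-in-
    Gini importances and exact per-class tree SHAP values feeding an iterative
    variable-screening loop that yields a minimal biomarker panel. A synthetic
    study generator with planted biomarkers makes every stage testable without
    access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
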
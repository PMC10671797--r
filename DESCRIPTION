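Package: robustdaa
Title: Robust Differential Abundance Analysis for Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential abundance analysis of taxa-by-sample microbiome
    count tables using centred log-ratio (CLR) linear models fitted by
    M-estimation. Supports squared-error (LinDA-style), Huber, Tukey
    bisquare and quantile losses with influence-function plug-in
    (sandwich) variances, kernel-mode bias correction of the
    compositional shift, t-based per-taxon tests, Benjamini-Hochberg
    adjustment and Cauchy combination across hyperparameter grids.
    Includes preprocessing (depth and prevalence filters, hybrid zero
    handling, winsorization) and a simulation engine with heavy-tailed
    error models and outlier injection for power/FDR evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
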
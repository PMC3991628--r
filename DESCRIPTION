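Package: panelmmc
Title: Multimarker Serum Biomarker Panels at Fixed Specificity by
    Metropolis-Monte-Carlo Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nested case-control biomarker studies: per-marker
    Mann-Whitney screening with Benjamini-Hochberg false-discovery control,
    empirical cut-points and sensitivity at a fixed specificity, exhaustive
    enumeration of 2-4 marker panels scored by a log-linear scoring function
    whose coefficients are assigned by Metropolis-Monte-Carlo optimization
    under repeated random subsampling cross-validation, McNemar and
    Hanley-McNeil comparison of correlated classifiers, biomarker-velocity
    regression against time to diagnosis, duplicate-sample coefficient-of-
    variation QC, and a blinded multi-step training/validation protocol.
    Includes a matched nested case-control cohort simulator with recorded
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
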
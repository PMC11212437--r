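Package: clrnet
Title: Penalized Conditional Logistic Regression with Block-Wise Elastic Net
    Penalties and Stability Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits conditional logistic regression models for matched
    case-control data (1:k matching) under elastic-net penalties that may
    differ between blocks of covariates, as arise when integrating multiple
    omics layers. Provides data-adaptive penalty-factor estimation, selection
    of the overall penalty level by cross-validated conditional
    log-likelihood, complementary-pairs stability selection for variable
    selection, a matched-data simulator, and a harness for power and false
    discovery rate studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC
Config/testthat/edition: 3
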
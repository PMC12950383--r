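Package: edam
Title: Equitable Donor Assessment Model for Deceased Donor Kidney Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Donor-only risk scoring of deceased donor kidneys with the
    Equitable Donor Assessment Model (EDAM). Implements the full derivation
    and validation pipeline: Aalen-Johansen cumulative incidence with
    competing death-with-function, jackknife pseudo-observations, a
    complementary log-log pseudo-value generalized linear model with robust
    (sandwich) standard errors approximating Fine-Gray subdistribution
    hazard regression, univariable screening, group-LASSO selection with
    BIC, post-selection refit, the frozen published 17-term score with its
    5-tier stratification, IPCW Harrell's C-index with bias-corrected
    bootstrap, decile calibration, internal-external cross-validation over
    geography-aligned super-regions with random-effects pooling, Gray's
    K-sample test, and KDPI reclassification analyses. A synthetic
    UNOS-like cohort simulator with a known Fine-Gray outcome process makes
    every stage testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cmprsk,
    metafor,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
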
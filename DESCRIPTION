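Package: eednet
Title: Bayesian Network Analysis of Diet, Gut Function, and Micronutrient
    Status in Multi-Site Child Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the nutrient density of complementary
    foods relates to environmental enteric dysfunction (EED) and to
    micronutrient deficiency in longitudinal multi-site infant cohorts.
    Provides a synthetic cohort generator with a known ground-truth
    directed acyclic graph; preprocessing of 24-h dietary recalls, fecal
    biomarkers (myeloperoxidase, neopterin, alpha-1-antitrypsin),
    dual-sugar permeability tests, and a 15-month blood panel into a
    standardized analytic dataset; univariate mixed-model screens with
    site as a random intercept; a Bayesian network fitted as conditionally
    independent generalized linear regressions by Gibbs sampling with
    Polya-Gamma augmentation for binary nodes; and a mediation layer
    comparing total with direct effects through the gut-function
    biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
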
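Package: itrforest
Title: Individualized Treatment Rules for Randomized Trials via
    Reinforcement Learning Trees with Treatment Muting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post hoc precision-medicine analysis of two-arm randomized
    clinical trials. Builds scaled univariate and hierarchical composite
    clinical rewards from baseline and follow-up outcomes, estimates an
    individualized treatment rule with a reinforcement-learning-tree
    regression forest whose progressive variable muting can remove the
    treatment indicator from whole regions of the covariate space,
    partitions participants into intervention, control and muted subgroups
    by plurality vote across multiply imputed datasets, evaluates rules
    against fixed all-intervention and all-control regimes with a
    normalized inverse-probability-weighted value estimator and bootstrap
    confidence intervals, and profiles the resulting subgroups with
    false-discovery-rate-adjusted baseline comparisons. Includes a
    calibrated synthetic-cohort generator with known ground-truth
    treatment-effect strata for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
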
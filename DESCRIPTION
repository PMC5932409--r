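Package: lgcmsens
Title: Change Sensitivity, Reliability, and Power for Latent Growth Curve Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and evaluating longitudinal study designs with
    linear latent growth curve models (LGCM). Computes the effective error of
    the slope-variance test, effective curve reliability (ECR), growth rate
    reliability (GRR), and the intraclass correlation of repeated measures;
    translates instrument reliability and test-retest stability coefficients
    into LGCM variance components for a-priori design planning; and estimates
    statistical power for likelihood ratio and Wald tests of zero slope
    variance both analytically (via the noncentral chi-square distribution and
    a power-equivalent minimal model) and by Monte Carlo simulation with full
    maximum-likelihood refitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
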
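Package: mrchain
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) along a causal
    chain: instrument selection and quality control for GWAS summary statistics
    (p-value thresholding, greedy LD clumping, weak-instrument F filtering,
    allele harmonization, Steiger directionality filtering), five causal-effect
    estimators (inverse-variance weighted with multiplicative random effects,
    MR-Egger, weighted median, simple and weighted mode), a sensitivity battery
    (Cochran's Q, Egger intercept, MR-PRESSO global/outlier/distortion tests,
    leave-one-out, scatter and funnel diagnostics), and a two-step
    product-of-coefficients mediation decomposition with delta-method standard
    errors. A synthetic three-layer GWAS generator (exposure, mediator, binary
    outcome via liability threshold) with a recorded ground truth makes every
    stage testable without external downloads, and a pipeline orchestrates the
    four-step exposure-mediator-outcome design over many traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
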
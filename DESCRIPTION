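Package: catbound
Title: Decision-Bound Modeling of Rule-Based and Information-Integration
    Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analyzing two-dimensional perceptual
    category learning experiments in the decision-bound tradition.  Defines
    rule-based and information-integration category structures as bivariate
    normal distributions over auditory (spectrotemporal ripple) and visual
    (Gabor patch) stimulus spaces, samples stimulus sets with a controlled
    category overlap, simulates cohorts of strategy-driven learners
    (including an ADHD-like group with delayed optimal-strategy adoption and
    higher decision noise), fits unidimensional rule, general linear
    classifier, and guessing observer models to each block of trials by
    maximum likelihood, selects per-block strategies by BIC, and derives
    strategy-use trajectories, learning curves, generalization-transfer
    scores, and symptom-performance correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
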
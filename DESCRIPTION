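Package: hetcube
Title: Integrated Heterogeneity Decomposition of Longitudinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose heterogeneity in longitudinal ordinal symptom
    data (persons x symptoms x time points) with three-mode principal component
    analysis (Tucker3), fitted by alternating least squares with fiber centering
    and slab normalization, a fit-percentage grid over component combinations
    with an elbow selection rule, and core-array interpretation tables. Also
    provides the single-slice latent variable baselines the multiway model is
    compared against: latent class analysis for ordinal items and latent-class /
    random-intercept growth mixture models on sum-score trajectories, compared
    via AIC and BIC. Includes seeded generators for QIDS-like synthetic data
    cubes with planted multiway structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
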
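Package: brainagegap
Title: Regularization, Bias Correction, and Effect Sizes for Brain-Age Gap Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when brain-age prediction models yield clinically
    useful brain-age gaps. Provides a synthetic cohort generator whose latent
    structure separates age-informative low-variance features from high-variance
    disease-sensitive features, standard-scaled ridge regression over a log-spaced
    regularization grid with exact leave-one-out and k-fold alpha selection,
    sample-level linear bias correction of brain-age gaps, caliper-based
    propensity-score matching with balance diagnostics, pooled-SD Cohen's d with
    bootstrap standard errors, regularization and train-size sweep experiments
    that locate accuracy-optimal and detection-optimal regimes, and exact additive
    (Shapley) feature attributions for the linear models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
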
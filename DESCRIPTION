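Package: gaitshift
Title: Intra-Individual Session Classification of Time-Continuous Gait Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying within-day changes of an individual's gait
    pattern across repeated measurement sessions. Provides a synthetic
    stride-curve generator with time-scale-structured session drift, the
    standard biomechanical preprocessing chain (stride segmentation,
    zero-phase Butterworth filtering, body-weight normalisation, time
    normalisation, z-transformation and range scaling), kernel-based
    discriminant regression and L2-regularised L2-loss linear support vector
    classifiers with one-versus-all multiclass wrappers, leave-one-out
    cross-validation designs (six-session and pairwise session
    classification) with hyperparameter grid search, time-interval
    aggregation of pairwise rates, and the accompanying nonparametric
    statistical layer (Shapiro-Wilk gating, repeated-measures ANOVA with
    Greenhouse-Geisser correction, Friedman and Wilcoxon signed-rank tests
    with Bonferroni correction and effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
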
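Package: emgdrift
Title: Multiday Surface-EMG Hand-Movement Classification Under Day-to-Day Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the long-term robustness of myoelectric
    pattern-recognition control. Implements a multiday synthetic surface-EMG
    generator with electrode-shift and gain drift between days, Butterworth
    high-pass preprocessing and overlapping-window extraction, the Hudgins
    time-domain feature set (MAV, WL, SSC, ZC), three classifier families
    (pooled-covariance LDA, stacked sparse autoencoders trained by scaled
    conjugate gradient, and a single-layer convolutional network trained by
    SGD with momentum), four cross-validation protocols (within-session,
    between-sessions, pairs-of-days, leave-one-day-out), and two-way ANOVA
    with Tukey HSD post hoc comparisons of classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
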
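Package: oculomap
Title: Multilevel Time-Scale Entropy and Lyapunov Maps for Eye-Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear time-series characterisation of eye-movement velocity
    recordings. Computes approximate entropy, fuzzy entropy and the largest
    Lyapunov exponent (Rosenstein-style, with false-nearest-neighbour and
    mutual-information embedding selection) over a dyadic multilevel
    time-scale map, assembles map cells into feature vectors, and classifies
    eye-movement events (saccadic latency, saccade, fixation segments) with
    a deterministic k-nearest-neighbour classifier under
    leave-one-session-out cross-validation. Includes a seeded generator of
    synthetic saccadic velocity series so the whole pipeline runs without an
    eye tracker.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
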
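Package: gazekmer
Title: K-Mer Analysis of Eye-Tracking Gaze Sequences Across Repeated Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts fixation streams from eye-tracking recordings into
    collapsed area-of-interest (AOI) dwell strings and quantifies expertise
    development across repeated trials with overlapping k-mer gaze patterns.
    Includes velocity-threshold (I-VT) fixation detection, AOI labeling with a
    whitespace fallback, dwell-string collapsing, k-mer counting and relative
    frequencies with a relevance filter, per-participant linear learning
    trends (slope and centered intercept), group learning curves, a
    statistical battery (Levene's test, paired first-vs-last-trial t-test with
    effect size r, two-group ANOVA), and a Markov-chain simulator generating
    synthetic multi-trial cohorts with expert-plateau and novice
    learning-curve dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
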
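Package: pdcsync
Title: Directed Interpersonal Physiological Synchrony via Windowed
    Partial Directed Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies directed interpersonal physiological synchrony
    between two or more interacting people from 1 Hz autonomic-arousal
    time series. Sessions are tiled into short windows; within each
    window a multivariate autoregressive model is fitted per pair of
    participants and Partial Directed Coherence (a frequency-domain
    formulation of Granger causality) yields one statistic per
    direction, tested against a Monte-Carlo surrogate null built by
    circular time-shifting. Includes session-level summaries (directed
    leading/pacing count tables, percent of session time in synchrony,
    episode aggregation, leading-role networks, between-session
    comparison), a window-length calibration procedure on null data,
    a ground-truth synthetic session generator, and a command-line
    interface.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
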
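Package: triadsync
Title: Body-Movement Synchrony Analysis for Triadic Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interpersonal body-movement synchrony in three-person
    conversations recorded on video. Extracts per-participant motion-energy
    time series from grayscale frame sequences by region-of-interest frame
    differencing, conditions them with a zero-phase low-pass Butterworth
    filter, and computes windowed dyadic correlations, lagged
    cross-correlation functions with peak value and peak lag, and a
    second-order (triadic) synchrony statistic on the windowed correlation
    series. Chance-level baselines are built from exhaustive surrogate
    pairings across conversations, and observed-versus-surrogate contrasts
    are tested with mixed-effects models with a paired-t fallback. A
    synthetic-corpus generator with a known common-drive coupling structure,
    colaughter bursts, covariates and game outcomes makes the full pipeline
    testable end to end.
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
    lme4,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
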
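Package: respirhythm
Title: Intermittent-Flow Respirometry, Metabolic Rhythms and Challenge
    Metrics for Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mass-specific oxygen consumption (MO2) of
    fish measured by intermittent-flow respirometry. Converts raw per-chamber
    oxygen traces organised in flush/wait/measure cycles into quality-filtered
    MO2 time series, and provides the downstream inference used in metabolic
    chronobiology and welfare studies: single-component cosinor regression
    with the zero-amplitude test, Sokolove-Bushell chi-square periodograms,
    daily waveforms and actogram matrices, continuous piecewise-linear
    (segmented) regression by exhaustive breakpoint search, random-intercept
    mixed models with backward selection and FDR-adjusted contrasts, and
    experiment-specific summaries (specific dynamic action, thermal Q10 and
    per-degree sensitivity, anesthetic recovery profiles). A synthetic-data
    generator reproduces the statistical structure of daily-rhythm, feeding,
    acute-stress, temperature-ramp and anesthetic-recovery experiments so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
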
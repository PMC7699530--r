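Package: exercea
Title: Lifetime Cost-Utility Modelling of Exercise After Early-Stage Breast Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A five-state Markov cohort model for the lifetime cost-utility
    analysis of a tailored exercise programme versus usual care for women
    after early-stage breast cancer, evaluated from a societal perspective
    in Australian dollars. Provides the cohort engine (yearly cycles,
    half-cycle correction, 5% discounting), parameter handling with
    beta/gamma/log-normal uncertainty distributions fitted by method of
    moments, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, one-way (tornado) sensitivity analysis,
    incremental cost-effectiveness ratios with dominance handling and
    percentile uncertainty intervals, plus bundled life-table and
    follow-up-cost fixtures, configuration I/O, broom-style tidiers and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
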
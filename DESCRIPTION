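Package: asrtlearn
Title: Simulation and Analysis of Implicit Probabilistic Learning in the
    Alternating Serial Reaction Time Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the Alternating Serial Reaction Time (ASRT) task:
    generation of probabilistic stimulus streams (including the
    reversed-sequence interference design), triplet classification with the
    exact high/low probability budget, simulation of synthetic participants
    with known learning parameters and obsessive-compulsive tendency scores,
    the standard trial-exclusion pipeline (response-time range, median
    absolute deviation, trill/repetition and block-initial removal),
    epoch-level learning and Old/New-knowledge difference scores, and the
    corresponding statistical layer (difference-score correlations,
    trial-level linear and generalized linear mixed models with Type III or
    likelihood-ratio inference, Sidak-adjusted cell contrasts, Nakagawa
    R-squared) together with a simulation harness for parameter recovery,
    type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    stats,
    utils,
    lme4,
    lmerTest,
    Matrix,
    car,
    emmeans,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
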
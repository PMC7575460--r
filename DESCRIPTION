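Package: gazetrigger
Title: Gaze-Triggered Looking-While-Listening Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing gaze-triggered
    looking-while-listening (LWL) eye-tracking experiments with infants.
    Generates counterbalanced 80-trial session schedules with yoked picture
    pairs and filler trials, runs the gaze-contingent target-selection state
    machine (including the bias-correction rules that keep every item labelled
    equally often), simulates infant gaze streams with known ground truth,
    extracts visual reaction times under the standard 300-1800 ms validity
    window, and computes the paradigm's reliability and validity statistics
    (paired t tests, Spearman rank correlations, split-half reliability, and
    two-stage trial-order and word-knowledge effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    lme4,
    lmerTest,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
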
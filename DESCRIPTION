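Package: scedtms
Title: Single-Case Multiple-Baseline Analysis of Corticospinal Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-case concurrent multiple-baseline
    exercise studies of corticospinal excitability. Derives transcranial
    magnetic stimulation (TMS) outcome measures (central motor conduction
    time, motor evoked potential amplitude and onset latency, resting motor
    threshold summaries), applies the six-feature visual analysis (level,
    trend, stability, variability, overlap, immediacy, percentage exceeding
    the median, consistency) that gates entry to inferential statistics, and
    estimates intervention effects with the nonoverlap-of-all-pairs statistic
    and exact or Monte-Carlo randomization tests with Bonferroni correction.
    Ships a synthetic-data generator that emulates a staggered concurrent
    multiple-baseline design so that every pipeline stage can be exercised
    and calibrated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
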
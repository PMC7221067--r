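Package: flymet
Title: Metabolic Rate, Activity and Lifespan Analysis for Fly Respirometry and Survival Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organismal metabolic phenotyping of insects from
    flow-through respirometry recordings and for cohort survival analysis.
    Converts 1-Hz CO2 traces into mass-corrected metabolic rate (linear
    baseline drift subtraction, ppm to uL/h to uW via an oxyjoule
    coefficient, allometric mass scaling), derives an absolute-difference-sum
    activity index, extracts standard metabolic rate, and tests metabolic
    homeostasis by regressing metabolic rate on activity per 5-min segment.
    Provides Kaplan-Meier estimation, log-rank and Gehan-Wilcoxon comparisons
    with multiple-testing correction, median and maximum lifespan summaries,
    a double-mutant additivity report, normality-gated statistical dispatch
    for phenotype measurements, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    survival,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    flexsurv,
    optparse,
    ggplot2
Config/testthat/edition: 3
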
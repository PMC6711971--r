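Package: crossbackr
Title: Crossover/Crossback Differential Analysis of Sperm RNA Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis of sperm RNA elements (REs) in two-arm
    crossover/crossback exposure studies. Fits per-feature linear
    mixed-effects models with subject-level random intercepts, derives
    permutation-based empirical P-values by within-subject label resampling,
    classifies features into the eight acute/recovery/continuous/reversal
    expression patterns, performs case-versus-control consensus calling with
    visit-replicate resampling, computes repeat-element delta-ratio
    enrichment with hypergeometric tests, and provides small-RNA
    condition-pooled differential testing. A synthetic-data generator
    emulates the crossover study design with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    lme4,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
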
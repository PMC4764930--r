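Package: moodnb
Title: Dynamical Network Biomarker Discovery by Multi-Objective
    Evolutionary Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies dynamical network biomarkers (DNBs) -- gene groups
    whose rising within-group correlation and variance, together with
    decorrelation from the rest of the transcriptome, provide an
    early-warning signal of an imminent critical transition -- from
    time-course case/control expression data. Implements the composite
    index combining within-group standard deviation, within-group and
    group-to-rest absolute Pearson correlation; a binary-encoded NSGA-II
    that searches gene subsets under a bi-objective formulation (strong
    signal now, quiet signal one time-point back); a distance-to-ideal
    significance test of each Pareto set against size-matched random gene
    sets; the preprocessing chain (probe aggregation, moderated Welch
    tests with FDR control, fold-change filtering, control-referenced
    normalization); a seeded synthetic-data generator with a planted DNB
    block; and hypergeometric gene-set enrichment.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
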
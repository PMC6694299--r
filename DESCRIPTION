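Package: tempoglia
Title: Temporal Pattern Analysis of Targeted Inflammation Count Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for NanoString nCounter-style targeted count
    panels profiled over a short post-injury time course (sham, 2, 14 and 60
    days post-injury). Implements control-based normalization (positive-control
    scaling, negative-control background subtraction, housekeeping scaling),
    per-gene negative-binomial GLM differential expression of each time point
    against sham with Benjamini-Hochberg adjustment, and pattern-oriented
    time-series clustering: min-max standardized group-mean trajectories,
    standardized linear changes (SLCs) between consecutive time points,
    discrete sub-pattern assignment (up, down, stable, noisy) against two
    relative-change cutoffs, and a sensitivity scan that selects the cutoff
    pair maximizing the p-measurement score. Includes a negative-binomial
    simulator with planted temporal patterns and full ground truth, gene-set
    heatmap matrices with gap-statistic k-means clustering, and a
    confidence-sum hub ranking for user-supplied interaction edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    cluster,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
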
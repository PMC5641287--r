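Package: gscd
Title: Calibration Set Optimization and Reliability Forecasting for
    Genomic Selection in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for forecasting the reliability of genomic predictions
    and optimizing calibration (training) sets in structured plant-breeding
    populations such as nested association mapping (NAM) designs. Implements
    the generalized coefficient of determination (CD) of arbitrary contrasts
    of genetic values under the G-BLUP mixed model, the family-aware criteria
    CDpop, CDpop_mean and CDallNAM, the mean-relatedness baseline Crit_Kin,
    and a stochastic exchange algorithm to select calibration sets that
    maximize any such criterion. Includes the VanRaden genomic relationship
    matrix, a Henderson mixed-model solver with optional REML estimation of
    the variance ratio, a doubled-haploid NAM simulator with Haldane
    recombination, and end-to-end evaluation scenarios comparing expected
    (CD-based) and observed prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
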
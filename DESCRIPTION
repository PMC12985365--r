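Package: pgsxe
Title: Polygenic Score by Environment Interaction Testing and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares three types of polygenic scores (PGS) for
    detecting polygenic gene-environment interaction (PGSxE) with a
    continuous exposure: marginal scores from standard genome-wide
    association scans (mPGS), interaction scores from genome-wide
    interaction scans (iPGS), and variance scores from variance-QTL scans
    (vPGS) using either the deviation regression model or a
    quantile-integral estimator. Provides pruning-and-thresholding score
    construction with interaction-based threshold optimization,
    cross-dataset weight harmonization, phenotype preprocessing rules for
    serum biomarkers and body-mass index, and a simulation engine for
    type-I-error and power evaluation under non-normal exposures,
    gene-environment correlation, and exposure measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quantreg,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    jsonlite,
    lmtest
Config/testthat/edition: 3
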
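Package: mrgrid
Title: Two-Sample Mendelian Randomization on GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: genetic-instrument selection (p-value thresholding, greedy LD
    clumping, proxy-variant substitution, F-statistic screening, confounder
    pruning against annotation lookups), allele harmonization with palindromic
    variant handling, causal-effect estimation by inverse-variance weighting,
    weighted median and MR-Egger regression, heterogeneity and horizontal
    pleiotropy diagnostics (Cochran's Q, Egger intercept test, MR-PRESSO
    global test), and orchestration of exposure-by-outcome analysis grids with
    direction-consistency and Bonferroni decision rules. Includes a synthetic
    summary-statistics generator with known causal truth for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
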
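Package: dcisgain
Title: Chromosomal Copy-Number Gain Scoring and Invasive-Cancer Risk in DCIS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking chromosomal copy-number gains (1q, 8q24,
    11q13 and HER2) measured by fluorescence in situ hybridization (FISH) in
    ductal carcinoma in situ (DCIS) to concurrent invasive breast cancer.
    Converts per-cell probe signal counts into per-locus gain calls with
    ratio-based scoring rules, assembles per-sample gain combinations and a
    mutually exclusive six-level gain category, computes diagnostic
    performance (sensitivity, specificity, predictive values, exact Fisher
    tests) and Wald odds ratios, fits complete-case multivariable logistic
    models by iteratively reweighted least squares, and reproduces an
    L1-regularized logistic feature-selection simulation over frequency-by-
    differential classes of genomic alterations. Includes a synthetic cohort
    generator emulating per-cell FISH counts and clinicopathologic covariates
    so that every stage is testable without access to raw tissue-microarray
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
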
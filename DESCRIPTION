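Package: metasnp
Title: Meta-Analysis of Case-Control SNP Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for pooling case-control genetic association studies of a
    biallelic variant: per-study log odds ratios under additive, dominant and
    recessive contrasts (including reconstruction of allele tables from sample
    sizes, minor-allele frequency and odds ratio when genotype counts are
    unavailable), Cochran's Q and I-squared heterogeneity testing,
    fixed-effect (inverse-variance and Mantel-Haenszel) and
    DerSimonian-Laird random-effects pooling with a heterogeneity-driven
    model-selection rule, subgroup and leave-one-out sensitivity analyses,
    Begg rank-correlation and Egger regression publication-bias tests,
    funnel and forest plot data, and a study simulator with known truth for
    calibration. Ships a transcribed 37-study roster for the BIN1 rs744373
    Alzheimer's disease association across East Asian and Caucasian
    populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
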
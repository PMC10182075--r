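Package: factorgwas
Title: Latent Genetic Factor GWAS from Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for cross-disorder genetic analysis from GWAS summary
    statistics. Estimates genetic covariance across case/control traits by
    multivariable LD-score regression with block-jackknife sampling
    covariance, fits confirmatory latent-factor models to the genetic
    covariance matrix by weighted least squares (with CFI and SRMR fit
    indices), runs factor-level GWAS with a Q_SNP heterogeneity test,
    defines and merges significant genomic regions, decomposes regions into
    conditionally independent signals by approximate conditional-and-joint
    analysis, groups signals across traits by Bayesian colocalization under
    the single-causal-variant assumption, and links signals to molecular
    QTLs via colocalization plus Wald-ratio Mendelian randomization. Ships
    a summary-statistics simulator with a known factor structure so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    ggplot2,
    readr,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
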
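Package: enclosabc
Title: Selection Coefficient Inference from Enclosure Experiments by
    Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulation of replicated seminatural
    enclosure populations segregating a wildtype and a knockout allele, driven
    by an observed demographic schedule (census sizes, sex ratios, scheduled
    cohort removals), together with an approximate Bayesian computation (ABC)
    framework to estimate sex-specific selection and dominance coefficients
    from allele- or genotype-frequency time series. Includes rejection
    sampling with ridge-regression posterior adjustment and
    heteroscedasticity correction, model choice by multinomial logistic
    regression, leave-one-out cross-validation, confusion matrices,
    goodness-of-fit testing, descriptive genotype-count statistics with
    Hardy-Weinberg tests, and a synthetic-data generator emulating the
    experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
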
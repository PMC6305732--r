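Package: focmshift
Title: Multivariate Analysis of Folate One-Carbon Metabolism and
    Transsulfuration Metabolite Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate analysis of plasma metabolite panels
    covering the folate-dependent one-carbon metabolism (FOCM) and
    transsulfuration (TS) pathways. Implements two-class Fisher
    discriminant analysis for separating case and control cohorts,
    Gaussian kernel density estimation of discriminant-score
    distributions with a balanced Type I/Type II error threshold,
    quantification of treatment effect as the shift in Type II error of a
    treated cohort's score density against a frozen reference threshold
    with bootstrap effect sizes, and Gaussian-kernel partial least
    squares regression predicting change in adaptive behavior from
    changes in metabolite measurements. Exhaustive variable-subset
    search, leave-one-out cross-validation, variable-frequency analysis,
    and a seeded synthetic cohort generator for end-to-end testing are
    included.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
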
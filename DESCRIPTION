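Package: mendelpower
Title: Power and Exact Burden Tests for Exome Sequencing of Rare
    Mendelian Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical design and analysis of case-only exome sequencing
    studies of rare monogenic Mendelian diseases. Implements the three
    gene-level burden statistics (total variant count, count of patients
    with at least two variants, and the collapsed count), their exact
    binomial null distributions with Bonferroni-corrected significance
    cutoffs and gene-length adjustment, analytic power under recessive and
    dominant inheritance with locus heterogeneity and imperfect mutation
    detection, and a cohort simulator for empirical validation of type-I
    error and power.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
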
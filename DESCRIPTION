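Package: famada
Title: Family-Based Adaptive Combination of P-Values for Rare-Variant
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region-based association testing for sequence data collected in
    pedigrees. Implements a kinship-adjusted retrospective score test per
    variant site, an adaptive truncated combination of per-site P-values
    (ADA), and a gene-dropping permutation null that randomises allelic
    transmission conditional on founder genotypes. Includes a family sequence
    simulator (single-tree coalescent haplotype pool, three-generation
    pedigree templates, dichotomous traits via PAR-derived genotype relative
    risks and continuous traits via per-QTL variance explained) and drivers
    for type-I error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
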
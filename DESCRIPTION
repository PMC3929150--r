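Package: segimpute
Title: Pedigree-Based Genotype Imputation of Non-Genotyped Individuals by
    Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes genotypes of non-genotyped individuals from genotyped
    relatives using single-locus iterative peeling (segregation analysis),
    with no linkage or linkage-disequilibrium information. Includes a
    gene-dropping simulator with founder haplotypes from a piecewise
    coalescent or a calibrated site-frequency model, scenario masking for
    livestock-style reference/test designs, imputation accuracy metrics
    based on genotype dosages corrected for mean gene content, and
    selection-index predictions of animal-specific imputation accuracy
    that treat gene content as a heritability-one trait.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
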
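Package: gentrial
Title: Genetic Variability Analysis for Multi-Environment Variety Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for randomized complete block design (RCBD)
    variety trials repeated over environments or years. Provides per-environment
    and combined analysis of variance with LSD mean separation and compact
    letter displays, method-of-moments variance components with broad-sense
    heritability, genotypic and phenotypic coefficients of variation and
    expected genetic advance under truncation selection, Pearson correlation
    with significance tests, genotype-by-trait principal component analysis
    with a loading-importance rule, and UPGMA hierarchical clustering of
    genotype means. Includes a synthetic multi-environment trial generator
    with known variance components and multi-trait genetic correlations so
    that every stage can be validated by parameter recovery, plus a reference
    cowpea trial summary dataset.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
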
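Package: adpgs
Title: APOE-Aware Polygenic Scores and Longitudinal Dementia Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Alzheimer's disease polygenic scores from GWAS summary
    statistics at a grid of p-value thresholds, with and without excision of
    the APOE/TOMM40/APOC1 linkage-disequilibrium block on chromosome 19
    (build 37), calls APOE epsilon-4 diplotypes from the rs429358/rs7412
    genotypes, classifies longitudinal cognition scores into
    dementia/CIND/normal with the Langa-Weir cut points, and fits
    repeated-measures logistic models of dementia via generalized estimating
    equations with robust (sandwich) standard errors. A synthetic-cohort
    generator emulates genotypes with linkage-disequilibrium blocks, discovery
    summary statistics, and a longitudinal dementia process, so the whole
    pipeline is testable without restricted cohort data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
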
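Package: adaptscape
Title: Landscape Genomics of Local Adaptation and Genomic Vulnerability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for landscape-genomic analyses of
    biallelic SNP data sampled across populations: SNP filtering and
    population-genetic summaries (nucleotide diversity, heterozygosities,
    Weir-Cockerham F_ST), F_ST-outlier scans (principal-component deviation
    and a Balding-Nichols F_ST/heterozygosity null) with an intersection
    rule for the neutral/outlier partition, Moran eigenvector maps and
    Mantel tests of isolation by distance and environment, partial-RDA
    variance partitioning, genotype-environment association via ridge LFMM
    and RDA loadings, gradient-forest turnover modelling of allele-frequency
    change along environmental gradients, and spatial genomic-vulnerability
    surfaces under future climates (local, migration-constrained forward and
    reverse genetic offsets, RGB composites, and the risk of non-adaptedness,
    RONA). Includes a synthetic-landscape generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
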
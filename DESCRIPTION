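Package: indelindex
Title: InDel Molecular Index Classification and Diversity Analysis for Rice Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for codominant InDel marker analysis of rice (Oryza sativa)
    germplasm panels. Scores band profiles against indica and japonica
    reference cultivars, computes the per-accession InDel molecular index
    (indica- and japonica-specific allele frequencies) and the associated
    seven-way subspecies classification, summarises per-marker
    informativeness (PIC, resolving power, effective multiplex ratio,
    marker index, rare alleles), partitions molecular variance between
    proposed populations with a permutation-tested Phi-PT, computes
    per-population diversity indices (Na, Ne, I, He, uHe), and explores
    panel structure through Jaccard/UPGMA clustering with cophenetic
    validation, covariance-based PCA and geographic PCoA. Includes a
    seedable synthetic panel generator for testing analyses when raw
    genotype data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    ape,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
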
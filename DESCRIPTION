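Package: coexmap
Title: Cross-Species Co-Expression Module Conservation and Tissue
    Specificity for Developmental Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for comparative transcriptomics of
    developmental time courses and tissue panels: mappability-corrected
    RPKM normalisation, fuzzy c-means soft clustering of stage profiles
    with membership-based core genes, weighted co-expression network
    modules via topological overlap, orthogroup-mediated cross-species
    module conservation scored by upper-tail hypergeometric tests,
    the tau tissue-specificity index, a shared-tissue expression filter,
    and phylostratigraphic gene-age assignment with Fisher enrichment.
    Includes a multi-species synthetic expression generator with planted
    modules, planted tissue-specific genes and an orthogroup/phylogeny
    scaffold so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    ape,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
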
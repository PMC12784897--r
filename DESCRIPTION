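Package: fishdiv
Title: Taxonomic and Phylogenetic Diversity of Reservoir Fish Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Multidimensional diversity analysis for freshwater fish
    surveys: taxonomic and phylogenetic alpha-diversity with
    tip-label-shuffling null models, pairwise Sorensen beta-diversity
    partitioned into turnover and nestedness at both taxonomic and
    phylogenetic levels, the beta-deviation contrast between the two
    levels, dominance scoring with the index of relative importance
    (IRI), and attribution of diversity patterns to environmental
    heterogeneity versus river distance via distance-decay regression and
    hierarchical partitioning. Ships a synthetic-data generator that
    emulates a dammed-reservoir survey design (sites ordered by distance
    to the dam) so the full pipeline can be exercised and tested without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
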
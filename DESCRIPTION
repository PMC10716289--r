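Package: epicontrast
Title: Comparative Epigenomics of Cultivar and Nitrogen Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for comparative epigenomics of crop cultivars
    profiled under contrasting nutrient regimes. Implements differential
    histone-mark quantitation with MA-trend normalization, chromatin-state
    dynamics scoring over fixed-width bins, distal peak-to-gene linkage with
    an empirical trans-chromosome null, Fisher-exact enrichment machinery
    (QTL overlap, gene-set overlap, motif enrichment with a position
    weight matrix scanner), cultivar-bias classification of nitrogen
    metabolism genes, and simple phenotype formulas (low-nitrogen response
    ratio of root traits, nitrate content). Ships a synthetic-data
    generator that plants known ground truth so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    IRanges,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
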
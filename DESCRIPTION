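Package: coexage
Title: Gene Co-Expression Modules Stratified by Evolutionary Gene Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from paired
    tumor/normal expression data, partitions them into modules, and classifies
    modules by the evolutionary age (unicellular versus multicellular origin)
    of their member genes. Quantifies how tumor-specific each module is with a
    novelty score based on overlap with reference modules, scores per-sample
    module activity with single-sample gene set enrichment, overlays somatic
    point mutations and focal copy-number alterations, computes intra-module
    gene centrality, and classifies tumor grade from module activity with
    random forests. Ships a paired tumor/normal cohort simulator with planted
    module, age, grade, and mutation structure so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    pROC,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
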
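Package: selforest
Title: Somatic Selection Inference and Transferable Random Forests for
    Cancer Driver Gene Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates long-term (cross-species) and short-term (somatic)
    evolutionary selection on mutated genes from tumour exome mutation
    calls, assembles mutation-distribution features (hotspots, truncation
    positions, mutation-class fractions), trains an introspectable CART
    random forest on labelled source-domain genes, and adapts it to an
    unlabelled target domain by distance-based structure reduction
    (pruning) and threshold shifting, to classify mutated genes as
    oncogenes, tumour suppressor genes or passengers. Includes a
    synthetic-data generator emulating source/target domains under
    covariate shift, a 20/20-rule baseline, and concordance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
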
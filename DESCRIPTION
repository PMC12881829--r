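Package: scPathAlign
Title: Pathway-Token Transformers for Zero-Shot Cell-Type Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates single-cell RNA-seq profiles by contrastively aligning
    a pathway-informed transformer encoder of gene expression with an encoder
    of free-text cell-type names in a shared embedding space. Genes are grouped
    into pathway "super tokens" (plus seeded random sets for pathway-orphan
    genes), embedded by expression-weighted averaging of learnable gene
    vectors, and encoded without positional information. Supports supervised
    classification, zero-shot annotation over arbitrary candidate name lists,
    entropy-based detection of unseen cell types, the associated evaluation
    metrics (micro and weighted-macro F1, seen/unseen/mixed F1, entropy-bin
    curves), prediction-augmented clustering, and a seeded synthetic
    scRNA-seq generator with pathway-structured type signatures and
    compositional cell names.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
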
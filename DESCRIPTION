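Package: spiderppi
Title: Supervised Prediction of Condition-Specific Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which edges of a general protein-protein interaction
    network are active in a given cell type or tissue. A graph-attention
    network with a permutation-invariant deep-set pair scorer is trained on
    gold-standard condition-specific interaction maps using per-condition
    gene-expression and protein-abundance profiles, cellular-localization
    vectors and interaction detection-assay features. The package also
    provides the classical unsupervised comparators (node removal, edge
    reweighting, calibrated co-abundance), ranking metrics and threshold
    selection, transfer learning to data-poor conditions, tissue-network
    validation against a tissue ontology, network propagation for
    disease-gene prioritisation, per-sample consensus networks and
    driver-gene enrichment, plus a synthetic-data generator with a planted,
    recoverable condition-specific interaction rule for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
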
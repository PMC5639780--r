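Package: hierDAG
Title: Hierarchical Ensemble Correction of DAG-Structured Ontology Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical top-down (HTD-DAG) and true-path-rule (TPR-DAG)
    ensemble methods that transform arbitrary per-term "flat" prediction
    scores over a DAG-structured ontology (such as the Human Phenotype
    Ontology) into scores guaranteed to obey the true path rule: every
    parent term scores at least as high as each of its children. Includes
    OBO parsing, annotation propagation and pruning, score normalization,
    gene-network construction and integration, CAFA-style gene-centric
    (Fmax) and term-centric (AUROC/AUPRC) evaluation, candidate-gene
    selection, and a synthetic-data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
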
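Package: simvec
Title: Polypharmacy Side-Effect Prediction for Weakly Connected Drugs via
    Similarity-Enhanced Knowledge-Graph Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting polypharmacy (drug-drug) side effects with
    trilinear knowledge-graph embeddings that stay informative for weakly
    connected ("new") drug nodes. Provides a heterogeneous drug/protein
    knowledge-graph store with uniform and weak-nodes evaluation splits,
    chemistry-aware node initialization from circular fingerprints, molecular
    descriptors or external hyperbolic embeddings, degree-inverse weighted
    drug-similarity edges, a three-step training loop with an anchor loss for
    weak drugs based on shared single side effects, cache-based negative
    sampling strategies, per-relation ROC/PR evaluation, and a seeded
    generator of synthetic Decagon-style benchmark graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
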
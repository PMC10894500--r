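Package: mirstress
Title: Predicting miRNA-Abiotic-Stress Associations with a GIN Graph Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts associations between plant microRNAs and abiotic
    stresses (drought, cold, salt, heat, ...) from a known association
    table and miRNA sequences. Computes five similarity networks (chaos
    game representation sequence similarity, Wang-style functional
    similarity, Gaussian interaction profile kernels for both node types,
    and word-embedding semantic similarity of stress terms), fuses them
    with the bipartite association matrix into a heterogeneous network,
    extracts random-walk-with-restart node features, and trains a graph
    autoencoder with a Graph Isomorphism Network encoder and an
    inner-product sigmoid decoder to reconstruct and rank candidate
    associations. Includes k-fold cross-validation with negative
    sampling, a synthetic benchmark generator with planted block
    structure, and a small pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
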
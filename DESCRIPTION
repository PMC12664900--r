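Package: spherepair
Title: Contrastive Hyperspherical Co-Embedding and Artificial Pairing of
    Single-Cell Multiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Co-embeds two or three single-cell data modalities measured in
    the same cells onto a common unit hypersphere using a contrastive
    variational autoencoder with a Power Spherical posterior, then pairs
    independent unimodal profiles through the learned space to generate
    artificial multiomics cells. Provides the spherical distributions and
    their closed-form KL divergence, the alternating adversarial training
    loop, pruned maximum-weight bipartite matching (with a chunked
    approximation and a randomized greedy tripartite variant), alignment
    metrics (FOSCTTM, graph iLISI, kNN accuracy, triplet similarity), and a
    fully seeded synthetic multiome generator for validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
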
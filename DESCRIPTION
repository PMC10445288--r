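Package: edgelinker
Title: Toxicant Signaling Network Reconstruction from Weighted Protein
    Interactomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs toxicant signaling networks by finding, for every
    edge of a weighted protein interactome, the best-scoring path through
    that edge from chemically responsive receptors to responsive
    transcription factors, and assesses each network against a
    degree-preserving permutation null with generalized-Pareto-refined
    p-values. Includes parsers for ToxCast-style hit/z-score matrices and
    CTD-style chemical-gene interaction tables, hypergeometric overlap
    evaluation, and a synthetic-data generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
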
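Package: kspathr
Title: Signaling Pathway Reconstruction by k-Shortest Paths in Weighted
    Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cell signaling pathways from a weighted directed
    protein interactome given only the pathway's receptors and downstream
    transcriptional regulators (TRs). Edge weights are interaction
    probabilities; a path's score is the product of its edge weights, and the
    k highest-scoring loopless receptor-to-TR paths are computed with Yen's
    algorithm accelerated by an exact A* heuristic on -log-transformed edge
    costs. Nodes and interactions are ranked by the index of the first path in
    which they appear. Also provides the evaluation machinery used to assess
    such reconstructions against curated pathways (negative subsampling,
    ranked precision-recall with block ties, pathway-adjacent-negative
    exclusion, distance-from-pathway, receptor/TR recovery ranks, role
    perturbation), a shortest-paths baseline, a random-walk-with-restarts
    baseline, and a seeded synthetic-fixture generator that plants
    elevated-weight pathways in random background networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
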
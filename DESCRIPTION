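Package: natvec
Title: Natural Vectors with Covariance Components for Alignment-Free
    Sequence Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free representation and comparison of nucleotide and
    protein sequences via natural vectors: per-letter counts, mean positions
    and second central moments of positions, extended with pairwise
    positional covariances (the 18-dimensional vector for DNA, 250 for
    proteins, and a k-mer generalization). Includes convex-hull disjointness
    testing of labeled families by linear-programming feasibility with
    SVM-based two-dimensional projections, nearest-neighbor typing,
    Euclidean and Hausdorff distance matrices, UPGMA tree construction with
    Newick output, a reference implementation of the older subset-averaged
    covariance definition, and a seeded generator of synthetic sequence
    families for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    e1071,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
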
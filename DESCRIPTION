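Package: sosreduce
Title: Information-Content-Based Reduction of Sparse Phylogenomic Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces sparse concatenated multi-gene alignments (supermatrices)
    to selected optimal subsets (SOS) of taxa and genes by combining data
    coverage with a quartet-based estimate of potential phylogenetic signal.
    Per-gene signal is estimated by geometry mapping of sampled taxon quartets
    onto the topology-support simplex using BLOSUM62-derived amino-acid
    distances; a deterministic hill-climbing procedure then eliminates
    low-content taxa and genes, maximising an optimality function that trades
    matrix information content against matrix size. Includes a simulator for
    sparse supermatrices (amino-acid sequence evolution along a tree with
    among-gene rate heterogeneity; Bernoulli and power-law missing-data
    regimes), threshold-based baseline reductions, quartet distances between
    trees, and bootstrap-support resolution scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
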
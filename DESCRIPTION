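Package: generearr
Title: Exact Gene-Order Rearrangement Distances and Parsimonious
    Mitochondrial Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares circular (and linear) mitochondrial gene orders under
    the three elementary rearrangements inversion, transposition and reverse
    transposition. Computes exact minimal rearrangement distances and the
    complete set of minimal evolutionary scenarios by depth-first backtracking
    with two admissible pruning tests (the shared-block property and the
    breakpoint lower bound), builds pairwise distance matrices with
    common-gene reduction and a fast-evolver removal rule, enumerates all
    most-parsimonious trees satisfying distance and monophyly constraints,
    exhaustively infers the gene orders of hypothetical ancestors at internal
    nodes, iterates tree enumeration against ancestor validation to obtain the
    complete solution set with its logical consequences, and reproduces
    random-genome distance distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
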
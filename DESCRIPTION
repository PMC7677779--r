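Package: labeledRF
Title: Generalized Robinson-Foulds Distance for Event-Labeled Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing phylogenetic trees whose internal nodes carry
    one of two event labels (speciation or duplication), as produced by gene
    tree reconciliation pipelines. Extends the Robinson-Foulds edit distance
    with three unit-cost operations on labeled trees: contraction of an edge
    joining two equally-labeled nodes, the inverse node extension, and a node
    label flip. Provides Newick/NHX input and output, bipartition and clade
    machinery, good/bad edge classification, maximal bad subtree
    decomposition, an optimal flip-minimizing tree contraction algorithm
    based on tree eccentricity, a factor-2 approximation heuristic for the
    labeled distance, an exact breadth-first-search distance for small trees,
    and a random-edit simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    ape,
    igraph,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
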
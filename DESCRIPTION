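Package: cocin
Title: Conserved Protein Complex Detection from Interolog Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies protein complexes conserved between two species by
    constructing an interolog network from two protein-protein interaction
    (PPI) networks and a many-to-many ortholog-group mapping, clustering the
    interolog network (maximal-clique merging or Markov clustering),
    projecting clusters back to per-species complexes, and evaluating the
    predictions against a Multi-set-Jaccard-derived gold standard of
    conserved complex pairs. Includes readers and writers for tab-separated
    PPI edge lists, OrthoMCL-style ortholog-group files and complex-catalog
    tables, an iterative Czekanowski-Dice edge-reliability weighting,
    a synthetic-scenario generator with planted conserved complexes for
    end-to-end benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
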
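Package: mycomotif
Title: Diamond-Motif Analysis of Tripartite Mycoheterotroph-Mycorrhizal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cheater (mycoheterotrophic) plants embed in
    mutualistic plant-arbuscular-mycorrhizal-fungus networks. Builds rarefied
    binary incidence networks from OTU read-count tables, computes plant- and
    fungus-level network descriptors (normalized degree, phylogenetic species
    variability, Jaccard and overlap similarity), runs Mantel and partial
    Mantel permutation tests for phylogenetic signal, and tests the
    diamond-shaped four-node module (two fungi sharing one mycoheterotrophic
    and one autotrophic plant) for overrepresentation against
    degree-proportional Bernoulli null models. Includes rarefaction and
    sample-resampling robustness ensembles and a synthetic-data generator
    emulating study-shaped datasets with controllable fungal preference and
    phylogenetic signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
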
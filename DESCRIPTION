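Package: qcfnet
Title: Level-1 Phylogenetic Network Inference from Quartet Concordance Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Composite (pseudo-)likelihood inference of semi-directed level-1
    phylogenetic networks from quartet concordance factors (CFs) estimated
    from gene trees under the multispecies network coalescent.  Provides
    quartet CF computation from gene trees, exact expected CFs for level-1
    quarnets, strict hill-climbing topology search with five rearrangement
    moves, seeded quartet subsampling and misfit-weighted move targeting,
    a coalescent gene-tree simulator on networks (Yule trees plus level-1
    reticulations), and hardwired-cluster network distances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
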
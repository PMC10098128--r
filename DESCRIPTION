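Package: phylocomb
Title: Partitioned-Model Combinability Testing for Organellar Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether multiple gene sets (for example plastid and
    mitochondrial gene alignments from the same taxa) share a single
    evolutionary history. Implements partitioned GTR+I+G maximum likelihood
    under edge-equal, edge-proportional, edge-unlinked and separate-tree
    linking schemes; an information-criterion combinability comparison that
    sums log-likelihood, site and parameter counts across separately
    modelled topologies; greedy partition merging; support-filtered
    Robinson-Foulds tree comparison and inverse-distance tree networks;
    bipartition-based gene-tree conflict tables; midpoint rooting with
    root-to-tip variance; and detection of clade-restricted shifts in
    nucleotide composition. Includes seeded synthetic-data generators that
    emulate a two-organelle study design so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
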
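Package: porephylo
Title: Phylogenetic Test of the Molecular-Piracy Hypothesis for Viral
    Potassium-Channel Pore Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for asking whether miniature viral K+
    channels were pirated from their algal hosts. Screens protein sets for
    K+ channel candidates by selectivity-filter motif (GYG/GFG/GLG) and
    hydropathy-based transmembrane topology, delineates the two-TM pore
    module, builds multiple sequence alignments, reconstructs phylogenies
    by four independent methods (neighbor joining, Fitch parsimony,
    pruning-algorithm maximum likelihood, and Bayesian MCMC over
    topologies), and turns the trees plus a viral/host label map into a
    quantitative monophyly verdict. Includes a sequence-evolution
    simulator that generates host paralog families and viral clades under
    piracy versus independent-origin scenarios with full ground truth, so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
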
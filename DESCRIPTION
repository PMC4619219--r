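Package: hicfold
Title: 3D Chromosome Structure Reconstruction from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("hicfold", "developers", email = "hicfold@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional models of individual chromosomes
    from intra-chromosomal Hi-C contact data. Contact lists are binned into
    symmetric interaction-frequency matrices, centromere gaps are removed,
    and matrices are optionally balanced (ICE or coverage normalization).
    Candidate bead-chain models are scored by a weighted combination of
    contact, non-contact, interaction-frequency and adjacent-distance
    satisfaction percentages, and refined by a three-stage stochastic
    optimizer: greedy adaptation moves, simulated annealing over a model
    ensemble, and a genetic algorithm with selection, crossover and
    score-gated mutation. Includes a synthetic ground-truth generator and
    the convergence and robustness-by-recovery validation protocols, plus
    PDB export of the final models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
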
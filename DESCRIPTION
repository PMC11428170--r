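Package: gdsfold
Title: Graph-Driven Sampling of Protein-Folding Pathways in Contact-Map Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates and analyses ensembles of protein-folding pathways for
    coarse-grained bead proteins by discrete optimization in inter-residue
    contact-map space. Implements the BLN (hydrophobic/hydrophilic/neutral)
    bead force field with thermostatted dynamics and simulated-annealing
    global search, the shortest-contact-hop (SCH) metric on contact maps,
    bit-flip simulated annealing over graph sequences, back-mapping of
    contact maps to Cartesian structures through one-sided harmonic graph
    restraints or crankshaft Monte Carlo, freezing-string and nudged-elastic-
    band path refinement, and clustering of order-parameter tracks with the
    discrete Frechet distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
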
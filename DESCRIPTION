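Package: oligonet
Title: Design and Kinetic-Dispersion Analysis of DNA Oligomer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing networks of interacting DNA oligomers with
    minimal unintended Watson-Crick pairing. Provides exhaustive enumeration
    of intra- and inter-oligomer duplex runs, 10^L window fitness scores (N,
    O, W_x) with necessary-duplex baselines, the "no 3's and no 8's" design
    rule, an evolution-inspired base-shuffling optimizer over domain-based
    designs, random-sampling scaling studies with power-law fits, bootstrap
    estimators of hybridization kinetic dispersion (interquartile range of
    log rate constants), and second-order/Arrhenius/compensation analysis of
    hybridization kinetics, plus design-file and FASTA input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
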
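Package: repkin
Title: Mean-Field and Stochastic Modeling of Inhomogeneous DNA Replication Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models eukaryotic DNA replication kinetics when origin-firing
    rates and fork velocities vary along the genome and through S phase.
    Provides a numerical solver for the coupled mean-field rate equations
    governing the replication fraction and the densities of left- and
    right-moving replication forks (including fork stalling at DNA defects
    and fork injection across the boundaries of a sub-genomic region), a
    lattice Monte Carlo simulator of single replication cycles, predictors
    of the summary profiles measured by single-molecule analysis of
    replicated DNA (SMARD) experiments, and a correlated least-squares
    fitting procedure, based on Cholesky decorrelation of simulated
    covariances, that infers initiation-rate and fork-velocity profiles
    from SMARD-like dual-label molecule data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
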
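Package: dnatorsion
Title: Coupled-Pendulum Simulation of DNA Torsional Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanical modelling of the rotational motion of nitrogenous
    bases around the sugar-phosphate backbone of double-stranded DNA. Each
    base is a pendulum attached to an elastic backbone and coupled to its
    Watson-Crick partner through the hydrogen-bond stiffness; the resulting
    2n Newton equations with velocity-proportional solvent dissipation and
    an external torque are integrated with a fixed-step fourth-order
    Runge-Kutta scheme. Includes sequence-to-coefficient mapping for A, C,
    G, T, viscosity sweeps of the mean angular deviation of a strand,
    oscillation-envelope damping metrics, synthetic sequence fixtures, and
    CSV/FASTA input and output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
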
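Package: bindkit
Title: Kinetic and Structural Analysis of Direct Protein-Protein Binding
Version: 0.9.0
Authors@R: person("bindkit", "maintainers", email = "bindkit@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying direct protein-protein interactions from
    three complementary experiment types. Surface plasmon resonance (SPR)
    sensorgrams are double-referenced and fit globally across analyte
    concentration series with a 1:1 Langmuir model that optionally includes a
    mass-transport step (two-compartment model), yielding association and
    dissociation rate constants, the equilibrium dissociation constant K_D,
    residual diagnostics, and replicate summaries. Two-chain coordinate
    frames (PDB, single or multi-MODEL) from molecular dynamics trajectories
    are post-processed into residue-level cross-molecule contact sites with
    per-frame occupancy, Coulomb electrostatic scores and a relative
    stability classification. Raw circular dichroism spectra are converted to
    molar ellipticity per residue. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
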
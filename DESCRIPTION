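Package: conformscape
Title: Conformational Landscape Analysis for Core-Plus-Appendage Proteins
Version: 0.1.0
Authors@R:
    person("Conformscape", "Developers", email = "conformscape@example.org",
           role = c("aut", "cre"))
Description: Trajectory-level analysis of protein conformational landscapes
    built around a rigid catalytic core carrying a mobile appendage domain,
    as in the DnaJB1-PKAc fusion kinase. Provides multi-model PDB input and
    output, Kabsch least-squares superposition, RMSD time series against a
    trailing-window average structure, per-residue RMSF and cross-construct
    differential RMSF, a three-angle (bend, elevation, shear dihedral)
    appendage mobility descriptor, GROMOS neighbor-count RMSD clustering
    with populations and representative frames, lag-1 conformational-state
    transition counting, holoenzyme placement with steric clash scanning,
    mono-exponential NMR T1/T2 relaxation fitting with rotational
    correlation time estimation, and seeded synthetic-data generators that
    exercise every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
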
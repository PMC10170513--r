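Package: metadrt
Title: Residence-Time Estimation from Metadynamics Unbinding Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for estimating ligand residence times (RT)
    from metadynamics simulations. Implements a well-tempered metadynamics
    engine over pluggable overdamped Langevin systems, center-of-mass
    collective variables (distance, angle, dihedral, RMSD) with an
    unbound-state detector, the conformational-flooding acceleration-factor
    estimator (RT = alpha x transition time), the t_META-D descriptor,
    replica statistics (geometric-mean tau, empirical cumulative
    distributions against Poisson curves, exponentiality checks, t-tests),
    and a structure-kinetics-relationship (SKR) regression layer with
    packaged reference tables for muscarinic M3 receptor antagonists.
    Columnar HILLS/COLVAR-style text files are read and written for
    interoperability with standard metadynamics post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
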
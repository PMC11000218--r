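Package: metadkin
Title: Thermodynamics and Kinetics of Ligand Release from Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ligand/product release studied by
    enhanced-sampling molecular dynamics. Implements volume-restrained
    well-tempered metadynamics on analytic Langevin model systems,
    time-independent (Tiwary-Parrinello) reweighting of the biased
    trajectories onto a free-energy surface over (distance, coordination
    number), bound/unbound region integration with the standard-state
    volume-entropy correction to obtain standard binding free energies and
    dissociation constants, and rate estimation from infrequent-metadynamics
    escape-time ensembles via Kramers' time-dependent rate theory:
    survivor-averaged maximum-bias fitting, maximum-likelihood estimation of
    the unbiased rate and bias-quality factor, Kolmogorov-Smirnov validation,
    and bootstrap uncertainty intervals. Reads and writes PLUMED-style
    COLVAR/HILLS whitespace tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
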
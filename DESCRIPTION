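Package: hetdiff
Title: Influence-Network Models of Heterogeneous CD4+ T-Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying induced heterogeneous differentiation of
    CD4+ T cells with sigmoidal influence-network ordinary differential
    equation models of a pair of master regulators. Provides the network
    dynamics (effective drives, Jacobians, integration, steady states,
    phenotype calling), multistability analysis (pseudo-arclength branch
    continuation with fold and pitchfork detection, criticality
    classification, fold-locus continuation and cusp estimation,
    bidirectional two-parameter stability diagrams), a cell-population
    simulator with parametric cell-to-cell variability under staged
    stimulus protocols, a population heterogeneity score, a library of
    calibrated generic and prototype motif models (Th1/Th2, Th1/Th17,
    iTreg/Th17), YAML/JSON model configuration files, CSV exports and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
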
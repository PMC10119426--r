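Package: qsarflow
Title: Combined 2D/3D QSAR Modelling with Heuristic Regression, Gene
    Expression Programming and CoMSIA Fields
Version: 0.1.0
Authors@R:
    person("QSAR", "Flow Developers", email = "qsarflow@example.org",
           role = c("aut", "cre"))
Description: Tools for small-molecule quantitative structure-activity
    relationship (QSAR) modelling of kinase-inhibitor potency.  Reads 3D
    structures (SDF, MOL2, XYZ) and IC50 activity tables, computes
    constitutional, charge and shadow-projection descriptors, searches
    multilinear models by a CODESSA-style heuristic stepwise procedure with
    leave-one-out cross-validation, evolves non-linear models by gene
    expression programming (Karva-encoded symbolic regression), builds
    CoMSIA-style Gaussian similarity-index fields with partial least squares
    regression, and validates all models against an external test set.
    Ships reproducible synthetic-data generators and a command-line
    pipeline so every stage is testable without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    digest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
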
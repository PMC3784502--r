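Package: dcx
Title: Rule-Based Kinetic Modeling of the Beta-Catenin Destruction Complex
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site-graph rule-based model of the Wnt/beta-catenin destruction
    complex (APC, Axin, beta-catenin, GSK-3beta, CK1alpha). Generates the full
    mass-action reaction network implied by a small set of binding,
    phosphorylation, synthesis and degradation rules, integrates the resulting
    stiff ODE system, and reproduces virtual experiments on normal and
    APC-truncated (SW480) cells: transfection scans with truncated APC
    constructs, pulse-chase half-lives, LiCl kinase inhibition, ablation of the
    cyclic core complex, and local sensitivity analysis. Includes behavioural
    calibration of unconstrained rate constants and a synthetic-data layer for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    lhs,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
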
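Package: inkflow
Title: Composition-to-Printability Modelling for Extrusion Bioprinting Inks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the printability of gelatin-sodium alginate-methylcellulose
    biomaterial inks from composition to toolpath. Fits the power-law
    (Ostwald-de Waele) constitutive model to rheometry curves, builds
    Box-Behnken response-surface models of the power-law index and consistency
    coefficient versus composition (with ANOVA, PRESS/predicted R-squared and
    backward elimination), solves steady laminar power-law flow through a
    barrel-plus-conical-tip nozzle by a quasi-1D lubrication closure, trains a
    sampled neural-network surrogate of the flow-rate surface over Latin
    hypercube designs, partitions the viscosity surface into printability
    regimes by k-means, and plans extrusion toolpaths with a slow-start scheme
    and controlled infill-to-frame overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
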
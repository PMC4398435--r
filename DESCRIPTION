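Package: lagoshift
Title: Dispersal-Constrained Bioclimatic Envelope Modelling with Joint
    Expert and Kappa Validation and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build presence-background species distribution
    models from occurrence records and gridded climate layers, evaluate
    them with threshold-dependent statistics (Cohen's kappa, the True
    Skill Statistic) under a joint expert-rating and kappa gate, project
    suitability under changed climates with dispersal-buffered minimum
    convex polygon clipping, quantify range, poleward and elevational
    change between periods, and relate predicted change to species
    traits with phylogenetically controlled generalized least squares
    (Pagel's lambda), AICc all-subsets ranking and model averaging. A
    virtual-species generator supplies every input with known ground
    truth so the whole pipeline can be validated against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    geosphere,
    ape,
    nlme,
    phytools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
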
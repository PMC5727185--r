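Package: plaquesim
Title: Individual-Based Simulation of Dental Plaque Dysbiosis Under Pulsed Sugar Intake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based (agent-based) reaction-diffusion model of
    supragingival dental plaque. Two functionally defined bacterial
    populations -- aciduric and non-aciduric cell aggregates -- compete for
    dietary glucose delivered in discrete pulses and for space in a biofilm
    of fixed thickness. Glycolysis follows Monod kinetics with a pH
    inhibition factor, lactic acid diffuses and sets the pH through buffered
    charge balance, and growth, division, stochastic death, phenotypic
    adaptation and mechanical relaxation of the sphere packing are resolved
    per particle. The package maps how the total daily amount of sugar
    versus its intake frequency drives biofilm dysbiosis, measured by the
    minimum pH at the enamel surface and the aciduric fraction of the
    community.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
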
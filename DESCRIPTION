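Package: rfablate
Title: Coupled Electro-Thermal Simulation of Bipolar Radiofrequency
    Renal Denervation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based finite-volume simulator for bipolar radiofrequency
    ablation of the renal artery wall and surrounding connective tissue.
    Solves the quasi-static electric potential on a labelled voxel grid,
    deposits Joule heat, advances the Pennes bioheat equation with optional
    perfusion and lumen blood advection, couples the two through a
    temperature-dependent tissue conductivity, and classifies the ablation
    zone with a temperature-threshold damage model.  Includes a
    thermochromic-phantom imaging module (HSB thresholding and area
    measurement at a known pixel scale) together with a synthetic phantom
    photograph generator for round-trip validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    png,
    tiff,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
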
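Package: voidnet
Title: Pore-Network Quantification of Porous Phases in Crystallized Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the porous (void) phase of shear-crystallized lipid
    networks imaged by X-ray micro-computed tomography. Segments grayscale
    volumes into void and solid by histogram-valley thresholding, extracts a
    pore-throat network with a maximal-ball discretization of the void
    (distance map, redundancy pruning, pores at local maxima and throats at
    saddles of the inscribed-sphere radius field), and computes morphology
    descriptors: void fraction, connectivity (mean pore coordination number),
    volume-weighted pore and throat radii (De Brouckere-type R43), and
    binned coordination and radius distributions. Includes seeded synthetic
    phantom generators for the three void morphologies observed in sheared
    lipids (disconnected spherical bubbles, planar crack networks,
    percolating sintered voids) so every stage is testable against known
    ground truth, and an assumption-gated ANOVA workflow (Brown-Forsythe
    gate, Tukey HSD or Welch with Dunnett T3) with compact-letter displays
    for comparing sample groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    graphics,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
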
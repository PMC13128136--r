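Package: borderfield
Title: Multicellular Phase-Field Simulation of Border Cell Cluster Migration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Energy-based multicellular phase-field model of collective border
    cell migration in the Drosophila egg chamber. Each cell (six nurse cells,
    the oocyte, and the border cell cluster as a single field) is a diffuse
    interface evolved by explicit gradient flow of a free energy with
    volume penalties, cell-cell exclusion, global chamber filling, and
    gradient-coupling adhesion. Steady chemoattractant landscapes (a
    geometry-shaped 1D channel profile extended to 2D, an analytic
    dorsal-biased field, scaled and uniform controls) drive guidance through
    either a classical chemotaxis force or a tangential interface migration
    (TIM) force in which saturating receptor activation converts contact with
    a substrate cell into traction along the interface. Includes scenario
    presets, trajectory analysis (centroid, speed, overlap, arrival), config
    and snapshot I/O, and small fixture scenes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
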
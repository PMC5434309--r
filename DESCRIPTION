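Package: microgrindr
Title: 3D Reconstruction and Morphometry from Serial Microgrinding Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rebuilding three-dimensional anatomy from serially
    ground, stained block-surface images. A resin-embedded specimen is ground
    away in thin runs; each exposed surface is stained, photographed and lost.
    The package recovers the full 3D pose of every surface from three vertical
    fiducial marks and per-run caliper thickness readings (including inclined
    grinding planes), segments tissue classes from stain colour, fuses the
    posed label maps into a voxel volume, extracts watertight surface meshes,
    and reports tetrahedral volumes, not-calcified fractions, channel
    diameters, wall thickness and diffusion-limit screening. A virtual
    grinding phantom simulator provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
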
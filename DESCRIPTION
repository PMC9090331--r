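Package: osmovol
Title: Mechano-Osmotic Modelling of Cell Volume Regulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling and analysing cell volume regulation under
    mechanical deformation. Implements the classical pump-and-leak model of
    osmotic volume control (steady state, Ponder passive response, and
    dynamic osmotic-shock simulation with regulatory adaptation), a
    mechanosensitive extension coupling membrane tension to ion transport
    through a Maxwell viscoelastic tension model, spherical-cap geometry
    linking cell-substrate contact area to total membrane area, a fitting
    pipeline for single-cell volume and spreading-area trajectories, a
    volume-fluctuation model for cells migrating through fibrous matrices,
    and seeded generators of synthetic single-cell measurements emulating
    fluorescence-exclusion volume and interference-contrast contact-area
    recordings.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
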
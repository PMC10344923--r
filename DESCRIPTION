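Package: activedrift
Title: Colloidal Transport in Light-Patterned Run-and-Tumble Bacterial Baths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of a two-dimensional bath of run-and-tumble
    spherocylindrical rods whose swimming speed is modulated in space by a
    virtual light pattern that follows a passive colloidal bead, together with
    the pressure-field analyses that explain the resulting bead drift: wall
    (mechanical) pressure resolved along the bead contour, spatially binned
    direct (virial) pressure, polarization and swim-force-density fields, the
    local momentum balance between the swim force density and the direct
    pressure gradient, drift-speed and region-density observables, closed-form
    ideal active-gas oracles, and deterministic synthetic fixtures for testing
    every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
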
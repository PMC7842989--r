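Package: mucoclear
Title: Mucociliary Clearance and Nasal Spray Drug Absorption Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of nasal spray drug absorption under
    mucociliary clearance. Spray droplet populations following a
    Rosin-Rammler size distribution deposit on an unwrapped
    two-dimensional nasal-wall surface with labelled anatomical regions,
    are advected by a mass-balanced, source-driven mucus surface velocity
    field, and release drug solute that diffuses through a one-dimensional
    mucus gel layer with an analytical Fourier-series absorption function.
    Solute diffusivity in the mucin gel follows the Obstruction-Scaling
    model on top of a Stokes-Einstein aqueous diffusivity. The package
    reports total and per-region absorbed dose as a function of solute
    radius, together with clearance trajectories and regional deposition
    bookkeeping, and can post-process externally computed deposition
    tables and surface velocity fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
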
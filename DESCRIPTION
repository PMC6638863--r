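Package: canopyrt
Title: Cohort-Based Two-Stream Canopy Radiative Transfer and Parameter
    Uncertainty Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves direct and diffuse shortwave (PAR and NIR) radiation
    profiles through height-ordered cohort canopies with a layered
    two-stream scattering scheme, and quantifies how uncertainty in ten
    radiative parameters (leaf and wood reflectance and transmittance per
    band, canopy clumping and leaf orientation) propagates to canopy
    albedo and absorbed PAR.  Includes prior distributions for temperate
    hardwood plant functional types, Gaussian-standard-deviation quantile
    sweeps, spline emulation, elasticity and variance-decomposition
    sensitivity analysis, bundled forest-inventory and synthetic canopy
    fixtures, a synthetic diurnal radiation generator, and an independent
    successive-orders-of-scattering verification solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
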
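Package: saxsgpa
Title: Guinier Peak Analysis and Shape Screening for Small-Angle X-Ray
    Scattering Curves
Version: 0.1.0
Authors@R:
    person("saxsgpa", "developers", email = "saxsgpa@example.org",
           role = c("aut", "cre"))
Description: Quality-control toolkit for one-dimensional small-angle X-ray
    scattering (SAXS) data built around Guinier peak analysis: transforms
    that turn the Guinier region of a scattering curve into a detectable
    peak, model-free scale-space peak localization, dimensionless
    validation of annotated radius of gyration and forward scattering,
    the elongation ratio shape statistic from pair-distribution
    functions, composite-angle shape clustering of Rg-normalized P(r)
    curves, and Hampel (median absolute deviation) outlier screening
    across curve collections.  Includes a synthetic generator for
    form-factor scattering and pair-distance distributions of regular
    solids (spheres, ellipsoids, cylinders, prisms), polydisperse
    populations and mixtures, so every analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
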
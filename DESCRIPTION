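Package: grcpl
Title: Piecewise-Linear Function Approximation with Granule-Cell Ramp Units
Version: 1.0.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Static model of the spinocerebellar system in which cerebellar
    granule cells act as thresholded ramp units reading linear projections of
    a multi-dimensional sensorimotor input space, and a Purkinje cell forms a
    signed linear readout of their activities.  The package fits such networks
    as piecewise-linear approximations of the non-linear inverse-dynamics
    terms of a planar two-joint arm, compares random against optimized
    projection directions, and reports the granule-cell capacity arithmetic
    implied by the curse of dimensionality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
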
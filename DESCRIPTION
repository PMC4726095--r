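Package: xpiv
Title: X-Ray Particle Image Velocimetry for Opaque Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring blood-flow velocity fields in optically opaque
    vessels from time series of X-ray phase-contrast projection images seeded
    with microbubble tracers. Implements the full measurement chain: image
    restoration (flat-field correction, background elimination by frame
    stacking, spatial-frequency band-pass), speckle quality metrics (speckle
    contrast, autocovariance speckle size, and the SR accuracy surrogate),
    two-frame zero-normalized cross-correlation velocimetry with subpixel peak
    localization and ensemble averaging, and inversion of line-of-sight
    "amassed" velocity profiles to recover the bluntness index K, maximum
    velocity, and volumetric flow rate, including a Stokes buoyancy
    correction for gas microbubbles. A seeded synthetic scene generator
    renders ground-truth-known microbubble image sequences so every stage is
    testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
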
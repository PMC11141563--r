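Package: crossvol
Title: Body Volume, Surface Area and Mass Estimation from Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the cross-sectional method (CSM) for estimating the
    volume, lateral surface area, mass and centre-of-mass plane of an animal
    body from a single silhouette view plus a series of measured
    cross-sections. Each body segment ("slab") between two measured sections
    is integrated in closed form after linear interpolation of shape ratios
    (area/identity-segment^2 and perimeter/identity-segment) across equal
    subslabs; terminal slabs may be treated as cones. Includes the two
    classical comparator methods (Graphic Double Integration with elliptical
    sections, and superellipse bracketing with k-value intervals), a density
    model with zero-density ellipsoidal voids, silhouette/section measurement
    from binary mask images, and a synthetic-solid fixture generator with
    exact reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
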
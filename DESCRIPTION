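Package: fazmetry
Title: Morphometry of Manually Segmented Foveal Avascular Zones in OCTA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying manual segmentations of the foveal
    avascular zone (FAZ) drawn over en-face optical coherence tomography
    angiography (OCTA) images. Extracts coloured perimeter overlays from
    annotated TIFF/PNG images, orders the boundary points azimuthally,
    computes polygon area by the shoelace (Gauss) method with pixel to
    square-millimetre conversion, and computes the acircularity statistic
    (radial coefficient of variation about the contour centre). Includes a
    synthetic-data module that generates FAZ-like harmonic contours with
    analytically known areas, renders annotated vessel-textured images, and
    simulates multi-observer tracing under two delimitation criteria, plus
    cohort-level aggregation of areas and acircularity by patient group,
    capillary plexus, observer and criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
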
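Package: unbendr
Title: Local Correction of Beam-Induced Sample Motion in Cryo-EM Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Motion correction for dose-fractionated cryo-EM movies with a
    focus on local, beam-induced sample deformation. Implements iterative
    full-frame cross-correlation alignment with interquartile-range outlier
    re-alignment, patch-based alignment of overlapping sub-regions, a 3D
    deformation model built from uniform cubic B-splines along the exposure
    axis and bicubic B-spline surfaces in-plane with free-end boundary
    conditions, least-squares and cross-correlation refinement of the model
    parameters, pixel-wise warping to a distortion-corrected micrograph,
    Green-Lagrange strain quantification of the corrected deformation, and
    two-dimensional template-matching signal-to-noise utilities. A seeded
    synthetic movie generator with known ground truth supports validation of
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
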
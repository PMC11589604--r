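Package: cystomap
Title: Cystoscopic Video Stitching into 2D Bladder Maps
Version: 0.1.0
Authors@R:
    person("Map", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds 2D composite "bladder maps" from sequential cystoscopic
    frames by scale/rotation-invariant feature matching and robust
    similarity/affine chaining, corrects accumulated drift via loop closures
    between spatially adjacent (non-consecutive) frames, and relocalizes
    frames of a later "revisit" video inside a previously built map,
    rendering position and orientation overlays. Includes pinhole camera
    calibration from checkerboard views with radial/tangential distortion,
    frame undistortion, a fully seeded synthetic phantom generator (vessel
    textures, scripted sweeps with ground-truth poses, checkerboard views)
    used as the test substrate, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    withr,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jpeg
Config/testthat/edition: 3
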
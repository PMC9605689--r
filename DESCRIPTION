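Package: compeye
Title: Compound-Eye Perspective Rendering and Eye-Design Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU renderer and analysis toolkit for arthropod compound-eye
    vision. Eyes are modelled as arbitrary collections of ommatidia, each an
    independent viewpoint sampling a cone of directions under a Gaussian
    acceptance function (full width at half maximum equal to the acceptance
    angle) by stochastic per-frame Monte-Carlo ray casting into triangle-mesh
    scenes loaded from glTF files. Includes human-viewable equirectangular
    spherical Voronoi projections of ommatidial views, a steradian-normalised
    variance calibration that selects the minimum samples-per-ommatidium for a
    target colour-noise level, environment variance maps with hotspot search,
    and a multilayer-perceptron localisation benchmark for comparing eye
    designs (full-surface, per-eye collapsed, and single-point variants) on
    synthetic scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
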
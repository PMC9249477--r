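Package: markercut
Title: Automatic-Marker Graph-Cut Segmentation and Imaging Scores for Bone CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary segmentation of grayscale bone CT slices by a seeded
    graph cut whose foreground/background seeds are generated automatically
    from a histogram threshold.  Implements maximum-entropy (Kapur) and
    minimum-error (Kittler-Illingworth, two-Gaussian) threshold selection,
    a two-terminal min-cut/max-flow segmenter with a bundled augmenting-path
    solver, Dice similarity and hole/isolated-component evaluation metrics,
    a deterministic phantom generator with exact ground truth, and a
    Rasmussen-style tibial-plateau imaging scoring system (articular surface
    displacement, damage-area and comminution sub-scores with grade mapping).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
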
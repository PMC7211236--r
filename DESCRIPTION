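Package: fmgda
Title: Frechet-Mean Grassmann Discriminant Analysis for Subspace Data
    and Single-Channel EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Supervised dimensionality reduction for points on the
    Grassmann manifold under the projection metric. Implements the
    Frechet subspace mean (top eigenvectors of the summed projectors),
    between-/within-class scatter surrogates, and an iterative
    trace-ratio solver that learns a linear map sending points of
    G(p, D) to a lower-dimensional Grassmannian G(p, d). Includes an
    EEG front-end that converts single-channel recordings (Bonn-style
    ASCII archives) into Grassmann points via short-time Fourier
    transform log-power spectrograms and SVD subspace embedding, a
    projection-metric nearest-neighbour classifier, experiment grids
    over train ratios and target dimensions, and seeded synthetic
    generators for both Grassmann class clouds and Bonn-like EEG
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
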
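Package: afmflex
Title: Flexible Fitting of Coarse-Grained Structures to AFM Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flexible-fitting molecular dynamics for high-speed atomic force
    microscopy (HS-AFM) height images. Provides coarse-grained Langevin
    dynamics under a structure-based (Go-type) protein potential, a
    Lennard-Jones stage wall and a cosine-similarity AFM bias potential;
    differentiable (smoothed) and hard-collision pseudo-AFM image renderers;
    stage-plane estimation and image leveling; and a region-restricted
    similarity-distribution procedure that infers which conformational state
    (e.g. lever-arm down-up versus down-down of a two-head-bound motor) an
    AFM frame represents. Includes a synthetic-data module generating toy
    filament-motor complexes and experimental-like noisy AFM images so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
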
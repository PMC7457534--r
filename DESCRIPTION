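Package: phenomesh
Title: Mesh-Based 3D Plant Phenotyping from Multi-View Turntable Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing triangle-mesh plant models reconstructed by
    turntable multi-camera photogrammetry. Provides mesh I/O (PLY/OBJ) and
    elementary geometry; a parametric broadleaf plant generator with exactly
    known ground-truth traits; a rig/turntable acquisition simulator with
    parallax-dependent depth noise and a consecutive-frame reconstruction
    rule; completeness segmentation of a model into stable, unstable and
    undetected regions with optimum viewing-zenith-angle selection; leaf and
    stem trait extraction (area, length, width, inclination, plant height,
    internode height and width); fusion of per-angle partial models by two
    strategies and tabulated error statistics against direct measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
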
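Package: fibreSR
Title: Unsupervised Super-Resolution for Fibre-Bundle Endomicroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training and evaluation tools for unsupervised
    super-resolution of probe-based confocal laser endomicroscopy (pCLE)
    images. Provides a physics-based acquisition simulator (Voronoi-cell
    fibre sampling with additive/multiplicative Gaussian signal noise and
    Delaunay-based linear reconstruction), an adversarial training scheme
    whose generator is constrained by a Voronoi-vectorization cycle
    consistency loss and a row/column-mean regularizer, synthetic study
    generation with video/patient grouping, and reference-free image
    quality metrics (SSIM, global contrast factor, composite score).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
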
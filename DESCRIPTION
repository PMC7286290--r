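Package: spimscreen
Title: Dual-View Light-Sheet High-Content Spheroid Screening Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of dual-view light-sheet (diSPIM) high-content
    screens of 3D spheroids: bead-based affine registration of the two views and
    point-spread-function extraction, joint Richardson-Lucy fusion and
    deconvolution, stage-drift tracking and correction, 3D nuclei segmentation
    with geometric and Haralick texture features, cell-cycle phase
    classification by a random forest on texture features or a compact
    VGG-style convolutional network on 2D slices with summed-likelihood voting,
    spheroid-level time-lapse quantification (counts, volumes, shape, growth
    rates, migration, phase transitions), and rank-based hierarchical
    phenotype clustering. A ground-truthed synthetic scene generator emulates
    H2B-labelled nuclei with phase-specific chromatin morphology, clonal
    spheroid growth, two orthogonal camera views, anisotropic optics, noise,
    fiducial beads and stage drift, so that every pipeline stage can be
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    withr,
    jsonlite,
    tiff,
    png,
    randomForest,
    EBImage,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'spimscreen-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'synthetic-scene.R'
    'render.R'
    'beads.R'
    'fusion.R'
    'segmentation.R'
    'haralick.R'
    'slices.R'
    'classify-rf.R'
    'classify-cnn.R'
    'classify.R'
    'benchmark.R'
    'spheroid.R'
    'phenotype.R'
    'layout.R'
    'io.R'
    'pipeline.R'
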
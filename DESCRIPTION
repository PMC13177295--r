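Package: mirsiprep
Title: Preprocessing and Sub-Band Analysis for Mid-Infrared Spectrochemical Imaging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantum-cascade-laser mid-infrared
    hyperspectral tissue images comparing fresh-frozen and formalin-fixed
    paraffin-embedded preparations: synthetic hyperspectral phantoms with
    known ground truth, Otsu tissue masking, background noise models,
    rubberband (convex-hull) baseline correction, Savitzky-Golay
    second-derivative spectra with edge trimming, 3-sigma significant-dip
    detection, band occurrence statistics, Gaussian sub-band fitting,
    composite-Simpson band integrals with percent-reduction statistics, and
    a Z-score/PCA/UMAP/logistic-regression spectral classification chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    glmnet,
    cluster,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'classification.R'
    'cube_io.R'
    'masking.R'
    'mirsiprep-package.R'
    'phantoms.R'
    'pipeline.R'
    'preprocess.R'
    'reduction_study.R'
    'spectral_axis.R'
    'subbands.R'
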
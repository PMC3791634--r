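Package: brainKSVM
Title: Wavelet Features and PSO-Tuned Kernel SVM for Brain MR Image
    Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid classifier for labelling axial T2-weighted brain MR
    slices as normal or abnormal. Features are the level-3 approximation
    coefficients of a decimated 2D Haar wavelet transform with symmetric
    boundary extension, reduced by principal component analysis to the
    smallest set of components preserving a target fraction of variance.
    A soft-margin support vector machine with a radial basis function
    kernel is trained by solving the dual quadratic program with a
    sequential minimal optimization solver, and its penalty C and kernel
    width sigma are tuned by particle swarm optimization driven by
    stratified 5-fold cross-validation accuracy. A seeded brain-phantom
    generator produces two-class synthetic image sets so the full
    pipeline is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
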
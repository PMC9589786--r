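Package: spectromesh
Title: Geometric Distortion Signatures of Spectrogram Surfaces for Audio
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents a one-dimensional audio signal (lung sounds, speech)
    by its spectrogram treated as a surface embedded in three-dimensional
    Euclidean space, triangulates the surface over a uniform time-frequency
    grid, flattens the mesh injectively into the plane by a Tutte
    (convex-combination) initialization followed by flip-free descent of the
    symmetric Dirichlet energy, and summarizes the geometric distortion of the
    flattening with eight closed-form energies of the per-triangle Jacobian
    singular values, aggregated by area-weighted averaging over low- and
    high-frequency triangle bands into a 16-dimensional shape signature.
    Includes Savitzky-Golay and MODWT wavelet denoising front ends, an MFCC
    statistical baseline, grouped train/test evaluation with a suite of
    classical classifiers, feature ranking, and seeded synthetic signal and
    mesh generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    nnet,
    rpart,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
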
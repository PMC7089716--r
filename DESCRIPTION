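Package: spectex
Title: Spectral CT Simulation, Texture-Prior Reconstruction and Texture-Based
    Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for photon-counting (multi-energy) computed tomography at
    desk scale: seeded generation of tissue-labeled phantoms and soft-tissue
    lesion cohorts, per-material CT-value-versus-energy spectral simulation,
    a parallel-beam forward/back projector with Poisson photon statistics,
    iterative reconstruction by SART and by a Bayesian low-rank plus
    tissue-specific Markov-random-field texture prior (LRTP) solved with an
    augmented-Lagrangian splitting, gray-level co-occurrence matrix and
    Haralick texture descriptors in 2D and 3D, a Gini-ranked random-forest
    lesion-classification harness with two-fold cross-validation, and image
    quality metrics (RMSE, PSNR, SSIM, FSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
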
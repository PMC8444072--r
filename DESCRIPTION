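Package: orthomoments
Title: Orthogonal Image Moments and Kernel Discriminant Classification
    for Biological Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction from biological images with discrete
    Krawtchouk moments and generalized pseudo-Zernike moments, including
    exact and approximate image reconstruction, reconstruction-based
    moment-order selection, and pose-normalized moment invariants. The
    extracted features feed a high-dimensional classification pipeline
    (Z-score scaling, t-statistic feature selection, Q-mode principal
    component analysis, Fisher linear discriminant analysis) and a
    Gaussian kernel density discriminant classifier that outputs class
    posterior probabilities. Classifier accuracy is summarized by a
    Bayesian beta posterior with credible intervals. Synthetic generators
    for wing-venation images with landmarks and for mammographic
    mass-like regions of interest with correlated categorical expert
    features support end-to-end evaluation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
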
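Package: spade
Title: Task-Related EEG Microstate Clustering with Spatial Patterns,
    Riemannian Distance, and a Deep Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Unsupervised segmentation of task-related multichannel EEG into
    microstates. Sliding-window spatial covariance matrices are compared with
    a generalized-eigenvalue spatial-pattern distance in sensor space and the
    affine-invariant Riemannian distance on the manifold of symmetric positive
    definite matrices; classical multidimensional scaling fuses the two
    distance structures with log-variance features into per-segment vectors,
    which are clustered by deep embedded clustering (autoencoder pretraining,
    K-means initialization, Student-t soft assignments, KL-divergence
    fine-tuning). Ships a simulated-EEG generator with per-sample ground-truth
    states, six baseline clustering algorithms, five evaluation metrics, and
    Riemannian-distance cluster-validation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
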
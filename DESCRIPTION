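Package: anmf
Title: Additional Neural Matrix Factorization for Computational Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts novel drug-disease treatment associations from a binary
    association matrix fused with drug-drug and disease-disease similarity
    matrices. Hidden features of drugs and diseases are extracted by
    denoising autoencoders that reconstruct both the interaction profile and
    the similarity vector; an elementwise-product single-layer perceptron
    (generalized matrix factorization) scores each pair, and all parameters
    are learned jointly by stochastic gradient descent over verified
    associations augmented with sampled negatives. Includes ten-fold
    cross-validation and new-drug (cold-start) evaluation protocols with
    AUC, AUPR and Hit-Ratio metrics, a planted-factor synthetic data
    generator, delimited-text readers and writers for the matrix inputs, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
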
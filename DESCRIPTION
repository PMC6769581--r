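Package: scdaimpute
Title: Reference-Free Genotype Imputation with Sparse Convolutional
    Denoising Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free imputation of missing genotype calls in
    samples-by-markers matrices. Implements a one-dimensional sparse
    convolutional denoising autoencoder (SCDA) that learns local linkage
    patterns through L1-regularized convolutional filters, together with
    three classical reference-free baselines (column average/mode,
    k-nearest-neighbour voting, and low-rank SVD completion fitted by an
    EM-style iteration), masking protocols for benchmark construction,
    simulators for linkage-structured genotype matrices, and a repeated-split
    evaluation harness that scores masked-entry imputation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
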
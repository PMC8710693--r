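Package: pmgae
Title: Pseudogene-miRNA Association Prediction via Similarity Fusion and a Graph Auto-Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pseudogene-miRNA associations in the competing
    endogenous RNA (ceRNA) network. Node similarities (generalized Jaccard,
    cosine and Pearson, computed from pseudogene expression profiles and
    miRNA 3-mer sequence profiles, with Gaussian interaction-profile kernel
    zero-filling) are fused by non-linear cross-diffusion, denoised with a
    stacked auto-encoder, and combined with the bipartite association graph
    in a two-layer graph-convolutional auto-encoder; node pairs are then
    classified with gradient-boosted trees. Includes five-fold
    cross-validation with edge masking, a leave-pseudogene-out case-study
    protocol, and a seeded synthetic-data generator with planted latent
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
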
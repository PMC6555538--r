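Package: lcsens
Title: Sparse Discriminative Latent Characteristics for Drug Sensitivity
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian nonparametric sparse discriminative factor analysis for
    multitask prediction of cancer drug sensitivity from genomic features.
    Drug-by-cell-line sensitivity scores are modeled through a small set of
    latent characteristics that load sparsely on drugs (via an Indian buffet
    process with spike-and-slab loadings) and are themselves sparse linear
    functions of expression, copy-number and mutation features. Optional
    Markov random field priors couple drugs sharing inhibition targets and
    features belonging to the same gene. Includes full Gibbs sampling
    inference, held-out cell-line prediction, cross-validated proportion of
    variance explained and concordance-index evaluation, per-characteristic
    drug-gene association tables, a generative simulator, active-area
    summarization of dose-response curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
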
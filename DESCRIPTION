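Package: mcglda
Title: Multiview Consensus Graph Learning for lncRNA-Disease Association
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between long noncoding RNAs (lncRNAs)
    and diseases from a sparse matrix of verified links. Several similarity
    views are built on each side of the bipartite network (ontology-based
    disease semantic similarity, lncRNA functional similarity, Gaussian
    interaction profile kernels, cosine similarity of interaction
    profiles); a row-stochastic consensus graph and simplex-constrained
    view weights are then learned jointly with the predicted association
    matrix by alternating optimization, with the prediction update solved
    in closed form as a Sylvester equation. Includes leave-one-out,
    k-fold, and leave-one-disease-out cross-validation with rank-based
    AUC, a planted-block synthetic data generator, and tidy accessors and
    plots for fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
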
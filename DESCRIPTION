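Package: chartstyle
Title: Stylometric Comparison of Clinical Note Documentation Styles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparison of free-text clinical documentation
    styles across author groups (specialty by generator, e.g. physician
    versus large-language-model). Provides pairwise structural similarity
    with translation-edit-rate (TER) edit-operation decomposition, BLEU,
    ROUGE-L and pluggable token-embedding similarity; Ward hierarchical
    clustering of note distance matrices; shared-vocabulary TF-IDF group
    keyword profiles; latent Dirichlet allocation topic profiles with
    group-size-normalised means; Shannon-entropy quantification of medical
    term variant diversity; a six-metric redundancy suite (sentence count,
    type-token ratio, inter-sentence similarity, DEFLATE compression
    ratio, unique words per sentence, bigram duplication); classical group
    statistics with Cliff delta effect sizes and false-discovery-rate
    correction; bootstrap downsampling sensitivity analysis; and a seeded
    synthetic note-corpus generator with controllable stylistic parameters
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
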
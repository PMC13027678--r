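#' Fit an LDA topic model over all notes
#'
#' Latent Dirichlet allocation fitted by a collapsed Gibbs sampler. Documents
#' are the bag of tokens after the same optional token filter used for
#' TF-IDF, so lexical and thematic profiles see the same vocabulary. The
#' sampler uses R's RNG, so a fixed seed reproduces the fit bit-identically.
#' Document-topic proportions and topic-word probabilities are the smoothed
#' count estimates from the final sweep.
#'
#' @param corpus A `note_corpus` with at least `K` documents.
#' @param K Number of topics (>= 2; default 3).
#' @param seed Integer RNG seed.
#' @param alpha Document-topic Dirichlet concentration (default `1/K`).
#' @param eta Topic-word Dirichlet concentration (default 0.01).
#' @param n_iter Gibbs sweeps (default 400).
#' @param filter Optional [token_filter()].
#' @return Object of class `topic_model` with `doc_topic` (notes x K, rows
#'   sum to 1), `topic_word` (K x vocabulary, rows sum to 1), `vocabulary`,
#'   `note_ids`, `seed`, `hyperparams`, `method`.
#' @export
fit_topics <- function(corpus, K = 3L, seed = 1L, alpha = 1 / K, eta = 0.01,
                       n_iter = 400L, filter = NULL) {
  if (K < 2) rlang::abort("K must be at least 2.")
  if (nrow(corpus) < K) rlang::abort("corpus must have at least K documents.")
  toks <- lapply(corpus$tokens, apply_token_filter, filter = filter)
  lens <- vapply(toks, length, 1L)
  if (all(lens == 0)) rlang::abort("degenerate corpus: all documents are empty.")
  vocab <- sort(unique(unlist(toks)))
  doc_id <- rep(seq_along(toks), lens) - 1L
  word_id <- match(unlist(toks), vocab) - 1L
  fit <- withr::with_seed(seed, cpp_lda_gibbs(
    doc_id, word_id, nrow(corpus), length(vocab), as.integer(K),
    alpha, eta, as.integer(n_iter)))
  doc_topic <- fit$doc_topic
  rownames(doc_topic) <- corpus$note_id
  colnames(doc_topic) <- paste0("topic_", seq_len(K))
  topic_word <- fit$topic_word
  colnames(topic_word) <- vocab
  rownames(topic_word) <- paste0("topic_", seq_len(K))
  structure(list(n_topics = as.integer(K), doc_topic = doc_topic,
                 topic_word = topic_word, vocabulary = vocab,
                 note_ids = corpus$note_id, seed = seed,
                 hyperparams = list(alpha = alpha, eta = eta,
                                    n_iter = as.integer(n_iter)),
                 method = "collapsed_gibbs"),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> K=%d, %d docs, |V|=%d (%s, seed=%d)\n",
              x$n_topics, nrow(x$doc_topic), length(x$vocabulary),
              x$method, x$seed))
  invisible(x)
}

#' Group-size-normalized mean topic distributions
#'
#' Per group, the arithmetic mean of member documents' topic proportions —
#' i.e. topic mass normalized by group size, so groups of very different
#' sizes are comparable. Each group vector remains on the simplex.
#'
#' @param model A fitted `topic_model`.
#' @param corpus The `note_corpus` the model was fitted on.
#' @return Matrix, groups x topics; rows sum to 1.
#' @export
group_topic_means <- function(model, corpus) {
  stopifnot(inherits(model, "topic_model"))
  if (!identical(model$note_ids, corpus$note_id)) {
    rlang::abort("model was not fitted on this corpus (note ids differ).")
  }
  gs <- corpus_groups(corpus)
  out <- t(vapply(gs, function(g) {
    idx <- corpus$group == g
    if (!any(idx)) rlang::abort(sprintf("group '%s' has no documents", g))
    colMeans(model$doc_topic[idx, , drop = FALSE])
  }, numeric(model$n_topics)))
  rownames(out) <- gs
  out
}

#' Top-probability words of one topic
#'
#' @param model A fitted `topic_model`.
#' @param topic Topic index in `1..K`.
#' @param k Number of words (capped at the vocabulary size); ties broken
#'   lexicographically.
#' @return Tibble with `rank`, `word`, `probability`.
#' @export
topic_top_words <- function(model, topic, k = 10L) {
  stopifnot(inherits(model, "topic_model"))
  if (topic < 1 || topic > model$n_topics) {
    rlang::abort(sprintf("topic index %d out of range 1..%d",
                         topic, model$n_topics))
  }
  p <- model$topic_word[topic, ]
  ord <- order(-p, names(p))
  kk <- min(k, length(p))
  tibble::tibble(rank = seq_len(kk),
                 word = names(p)[ord][seq_len(kk)],
                 probability = unname(p[ord][seq_len(kk)]))
}
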
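#' Token filter: multiword merging and stoplist removal
#'
#' Rule-based preprocessing applied before TF-IDF and topic fitting. Multiword
#' expressions are merged longest-first into single tokens joined with `_`
#' (e.g. `c("major", "depressive", "disorder")` becomes
#' `"major_depressive_disorder"`), then stoplist tokens are dropped. The
#' default filter is a no-op: the stoplist is empty because non-informative
#' tokens are corpus-specific and must be user-supplied.
#'
#' @param stoplist Character vector of tokens to drop.
#' @param merge_expressions Character vector of space-separated multiword
#'   expressions to merge.
#' @return An object of class `token_filter`.
#' @export
token_filter <- function(stoplist = character(0),
                         merge_expressions = character(0)) {
  exprs <- lapply(merge_expressions, function(e)
    stringi::stri_split_regex(e, "\\s+")[[1]])
  exprs <- exprs[order(-vapply(exprs, length, 1L))]
  structure(list(stoplist = stoplist, expressions = exprs),
            class = "token_filter")
}

apply_token_filter <- function(tokens, filter) {
  if (is.null(filter)) return(tokens)
  stopifnot(inherits(filter, "token_filter"))
  if (length(filter$expressions) > 0 && length(tokens) > 0) {
    out <- character(0)
    i <- 1L
    n <- length(tokens)
    while (i <= n) {
      merged <- FALSE
      for (e in filter$expressions) {
        le <- length(e)
        if (i + le - 1L <= n && all(tokens[i:(i + le - 1L)] == e)) {
          out <- c(out, paste(e, collapse = "_"))
          i <- i + le
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        out <- c(out, tokens[i])
        i <- i + 1L
      }
    }
    tokens <- out
  }
  tokens[!tokens %in% filter$stoplist]
}

#' Fit a shared-vocabulary TF-IDF model over the whole corpus
#'
#' One vectorizer is fitted on the concatenation of all groups so that
#' vocabulary and IDF weights are shared — group profiles computed from the
#' same model are directly comparable. Two weighting variants are available:
#'
#' * `paper_formula` (default): raw term count times `log(N / DF(t))`, no
#'   vector normalization. A term present in every document scores exactly 0.
#' * `smoothed_library`: the common library weighting,
#'   `tf * (log((1 + N) / (1 + DF)) + 1)` with L2 normalization per document.
#'
#' @param corpus A `note_corpus`.
#' @param variant `"paper_formula"` or `"smoothed_library"`.
#' @param filter Optional [token_filter()].
#' @param log_base Logarithm base for `paper_formula` (default `exp(1)`).
#' @return Object of class `tfidf_model` with `vocabulary`, `doc_freq`,
#'   `n_docs`, `variant`, `log_base`.
#' @export
fit_tfidf <- function(corpus, variant = c("paper_formula", "smoothed_library"),
                      filter = NULL, log_base = exp(1)) {
  variant <- match.arg(variant)
  if (nrow(corpus) == 0) rlang::abort("corpus is empty.")
  toks <- lapply(corpus$tokens, apply_token_filter, filter = filter)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) {
    rlang::abort("vocabulary is empty after token filtering.")
  }
  df <- integer(length(vocab))
  names(df) <- vocab
  for (t in toks) {
    u <- unique(t)
    df[u] <- df[u] + 1L
  }
  structure(list(vocabulary = vocab, doc_freq = df, n_docs = nrow(corpus),
                 variant = variant, log_base = log_base, filter = filter),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model> variant=%s N=%d |V|=%d\n",
              x$variant, x$n_docs, length(x$vocabulary)))
  invisible(x)
}

# Dense TF-IDF score vector for one token sequence under a fitted model.
# Out-of-vocabulary tokens are ignored.
tfidf_scores <- function(model, tokens) {
  tokens <- apply_token_filter(tokens, model$filter)
  v <- numeric(length(model$vocabulary))
  names(v) <- model$vocabulary
  tokens <- tokens[tokens %in% model$vocabulary]
  if (length(tokens) == 0) return(v)
  tf <- table(tokens)
  terms <- names(tf)
  if (model$variant == "paper_formula") {
    idf <- log(model$n_docs / model$doc_freq[terms]) / log(model$log_base)
    v[terms] <- as.numeric(tf) * idf
  } else {
    idf <- log((1 + model$n_docs) / (1 + model$doc_freq[terms])) + 1
    v[terms] <- as.numeric(tf) * idf
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

#' Mean TF-IDF profile of one author group
#'
#' Per-term arithmetic mean of the document TF-IDF scores over the group's
#' notes, under the shared model, with the top-`k` terms ranked descending
#' (ties broken lexicographically).
#'
#' @param model A fitted `tfidf_model`.
#' @param corpus The `note_corpus` the model was fitted on.
#' @param group Group label.
#' @param k Number of top terms to report (default 10).
#' @return Object of class `group_term_profile`: list with `group`, `scores`
#'   (named numeric vector over the full vocabulary) and `top_k` (tibble with
#'   `rank`, `term`, `mean_tfidf`).
#' @export
group_profile <- function(model, corpus, group, k = 10L) {
  stopifnot(inherits(model, "tfidf_model"))
  notes <- group_notes(corpus, group)
  mat <- vapply(notes$tokens, function(t) tfidf_scores(model, t),
                numeric(length(model$vocabulary)))
  scores <- if (is.matrix(mat)) rowMeans(mat) else mat
  names(scores) <- model$vocabulary
  ord <- order(-scores, names(scores))
  kk <- min(k, length(scores))
  top <- tibble::tibble(
    rank = seq_len(kk),
    term = names(scores)[ord][seq_len(kk)],
    mean_tfidf = unname(scores[ord][seq_len(kk)])
  )
  structure(list(group = group, scores = scores, top_k = top,
                 variant = model$variant),
            class = "group_term_profile")
}

#' @export
print.group_term_profile <- function(x, ...) {
  cat(sprintf("<group_term_profile> group=%s (variant=%s)\n", x$group, x$variant))
  print(x$top_k)
  invisible(x)
}

#' TF-IDF top-term table for every group
#'
#' @inheritParams group_profile
#' @return Tibble with columns `group`, `rank`, `term`, `mean_tfidf`.
#' @export
group_profile_table <- function(model, corpus, k = 10L) {
  do.call(rbind, lapply(corpus_groups(corpus), function(g) {
    p <- group_profile(model, corpus, g, k)
    cbind(group = g, p$top_k)
  }))
}
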
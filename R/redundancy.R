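REDUNDANCY_METRICS <- c("n_sentences", "ttr", "inter_sentence_redundancy",
                        "compression_ratio", "unique_words_per_sentence",
                        "bigram_duplication")

# Smoothed TF-IDF sentence vectors local to one note, then the mean cosine
# distance over unordered distinct sentence pairs. Smoothed IDF is required
# here: under the raw-count formula a term present in every sentence would
# get weight 0 and identical sentences would produce undefined cosines.
inter_sentence_similarity <- function(sentences) {
  s <- length(sentences)
  if (s < 2) return(0)
  vocab <- sort(unique(unlist(sentences)))
  df <- table(factor(unlist(lapply(sentences, unique)), levels = vocab))
  idf <- log((1 + s) / (1 + as.numeric(df))) + 1
  names(idf) <- vocab
  mat <- vapply(sentences, function(toks) {
    v <- numeric(length(vocab))
    names(v) <- vocab
    tf <- table(toks)
    v[names(tf)] <- as.numeric(tf) * idf[names(tf)]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }, numeric(length(vocab)))
  cos <- crossprod(mat)
  mean_dist <- mean(1 - cos[upper.tri(cos)])
  1 - mean_dist
}

#' Six-metric redundancy profile of one note
#'
#' Computes, from a single note: the sentence count; the type-token ratio
#' (unique tokens over total tokens); inter-sentence redundancy (1 minus the
#' mean pairwise cosine distance between TF-IDF sentence vectors fitted
#' within the note; 0 when the note has fewer than two sentences); the
#' DEFLATE compression ratio (compressed over original size of the UTF-8
#' bytes of the normalized text — repetitive text compresses further, giving
#' a lower ratio); the mean number of unique words per sentence; and the
#' bigram duplication rate (1 minus unique over total adjacent token pairs;
#' 0 when the note has fewer than two tokens).
#'
#' @param note One-row slice of a `note_corpus` (or a list with `tokens`,
#'   `sentences`, `norm_text`).
#' @param compressor_level DEFLATE level 1-9 (default 6). Compression ratios
#'   are compressor-dependent; compare only profiles computed at the same
#'   level.
#' @return One-row tibble with the six metrics.
#' @export
redundancy_profile <- function(note, compressor_level = 6L) {
  if (inherits(note, "note_corpus") || is.data.frame(note)) {
    stopifnot(nrow(note) == 1)
    tokens <- note$tokens[[1]]
    sentences <- note$sentences[[1]]
    norm_text <- note$norm_text[[1]]
  } else {
    tokens <- note$tokens
    sentences <- note$sentences
    norm_text <- note$norm_text
  }
  if (length(tokens) == 0) rlang::abort("redundancy profile needs >= 1 token.")
  n_sent <- length(sentences)
  ttr <- length(unique(tokens)) / length(tokens)
  redund <- inter_sentence_similarity(sentences)
  bytes <- charToRaw(enc2utf8(norm_text))
  comp <- cpp_deflate_size(bytes, as.integer(compressor_level)) / length(bytes)
  uwps <- if (n_sent > 0) {
    mean(vapply(sentences, function(s) length(unique(s)), numeric(1)))
  } else 0
  n_tok <- length(tokens)
  bigram_dup <- if (n_tok < 2) 0 else {
    bg <- paste(tokens[-n_tok], tokens[-1], sep = "␟")
    1 - length(unique(bg)) / length(bg)
  }
  tibble::tibble(
    n_sentences = n_sent,
    ttr = ttr,
    inter_sentence_redundancy = redund,
    compression_ratio = comp,
    unique_words_per_sentence = uwps,
    bigram_duplication = bigram_dup
  )
}

#' Redundancy profiles for every note in a corpus
#'
#' @param corpus A `note_corpus`.
#' @param compressor_level Passed to [redundancy_profile()].
#' @return Tibble, one row per note, with `note_id`, `group` and the six
#'   metrics.
#' @export
corpus_redundancy <- function(corpus, compressor_level = 6L) {
  profs <- lapply(seq_len(nrow(corpus)), function(i)
    redundancy_profile(corpus[i, ], compressor_level))
  cbind(tibble::tibble(note_id = corpus$note_id, group = corpus$group),
        do.call(rbind, profs))
}

#' Per-group aggregation of the redundancy metrics
#'
#' Mean, standard deviation and median of each of the six metrics within
#' each author group, in a fixed metric order.
#'
#' @inheritParams corpus_redundancy
#' @return Tibble with `group`, `metric`, `mean`, `sd`, `median`.
#' @export
group_redundancy <- function(corpus, compressor_level = 6L) {
  profs <- corpus_redundancy(corpus, compressor_level)
  rows <- list()
  for (g in corpus_groups(corpus)) {
    sub <- profs[profs$group == g, , drop = FALSE]
    for (m in REDUNDANCY_METRICS) {
      x <- sub[[m]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, metric = m, mean = mean(x),
        sd = if (length(x) > 1) sd(x) else 0, median = median(x))
    }
  }
  do.call(rbind, rows)
}
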
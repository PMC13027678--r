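#' Translation edit rate between two token sequences
#'
#' Minimal number of word-level insertions, deletions and substitutions (unit
#' costs, no shift/reorder operation) needed to transform `hyp` into `ref`,
#' divided by the reference length. Lower values indicate higher structural
#' similarity; the score can exceed 1 when the hypothesis is much longer than
#' the reference. The edit script is canonical: the backtrace prefers
#' match/substitution over deletion over insertion, so the operation
#' decomposition is reproducible.
#'
#' @param hyp Character vector of hypothesis tokens.
#' @param ref Character vector of reference tokens; must be non-empty.
#' @return List with `score` and `ops`, where `ops` has fields `insertions`,
#'   `deletions`, `substitutions`, `ref_length`, `hyp_length`. The balance
#'   `insertions - deletions == ref_length - hyp_length` always holds.
#' @examples
#' ter(c("a", "b", "c", "d"), c("a", "b", "c"))$score  # 1/3
#' @export
ter <- function(hyp, ref) {
  if (length(ref) == 0) rlang::abort("TER is undefined for an empty reference.")
  hyp <- as.character(hyp)
  ref <- as.character(ref)
  vocab <- unique(c(hyp, ref))
  res <- cpp_edit_ops(match(hyp, vocab), match(ref, vocab))
  ops <- list(
    insertions = res[[2]],
    deletions = res[[3]],
    substitutions = res[[4]],
    ref_length = length(ref),
    hyp_length = length(hyp)
  )
  list(score = res[[1]] / length(ref), ops = ops)
}

count_ngrams <- function(tokens, n) {
  len <- length(tokens) - n + 1L
  if (len <= 0L) return(integer(0))
  grams <- vapply(seq_len(len), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = "␟"), character(1))
  table(grams)
}

#' Sentence-level BLEU
#'
#' Geometric mean of modified n-gram precisions up to `max_n`, multiplied by
#' the brevity penalty `min(1, exp(1 - ref_len/hyp_len))`. The effective
#' maximum order is capped at the shorter sequence length so very short pairs
#' are comparable. With `smoothing = "epsilon"`, zero n-gram match counts are
#' replaced by `epsilon` before dividing; with `"none"` any zero precision
#' makes the score 0.
#'
#' @param hyp,ref Non-empty character vectors of tokens.
#' @param max_n Maximum n-gram order (default 4).
#' @param smoothing `"epsilon"` (default) or `"none"`.
#' @param epsilon Smoothing constant for zero match counts (default 0.1).
#' @return Score in \[0, 1\].
#' @export
bleu <- function(hyp, ref, max_n = 4L, smoothing = c("epsilon", "none"),
                 epsilon = 0.1) {
  smoothing <- match.arg(smoothing)
  if (length(hyp) == 0 || length(ref) == 0) {
    rlang::abort("BLEU is undefined for empty token sequences.")
  }
  stopifnot(max_n >= 1)
  n_eff <- min(max_n, length(hyp), length(ref))
  log_p <- numeric(n_eff)
  for (n in seq_len(n_eff)) {
    hg <- count_ngrams(hyp, n)
    rg <- count_ngrams(ref, n)
    common <- intersect(names(hg), names(rg))
    clipped <- sum(pmin(hg[common], rg[common]))
    total <- sum(hg)
    if (clipped == 0) {
      if (smoothing == "none") return(0)
      clipped <- epsilon
    }
    log_p[n] <- log(clipped / total)
  }
  bp <- if (length(hyp) >= length(ref)) 1 else exp(1 - length(ref) / length(hyp))
  bp * exp(mean(log_p))
}

#' ROUGE-L: longest-common-subsequence F-measure
#'
#' Precision is LCS length over the length of `a`, recall over the length of
#' `b`; the weighted F-measure uses `beta` (default 1, i.e. F1). With
#' `beta = 1` the score is symmetric in its arguments.
#'
#' @param a,b Non-empty character vectors of tokens.
#' @param beta Recall weight.
#' @return Score in \[0, 1\].
#' @examples
#' rouge_l(c("a", "b", "c"), c("a", "c"))  # 0.8
#' @export
rouge_l <- function(a, b, beta = 1) {
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("ROUGE-L is undefined for empty token sequences.")
  }
  vocab <- unique(c(a, b))
  lcs <- cpp_lcs_length(match(a, vocab), match(b, vocab))
  if (lcs == 0) return(0)
  prec <- lcs / length(a)
  rec <- lcs / length(b)
  (1 + beta^2) * prec * rec / (rec + beta^2 * prec)
}

#' Deterministic hash-seeded embedding backend
#'
#' Offline stand-in for a pretrained contextual encoder: each distinct token
#' string is mapped to a fixed pseudo-random unit vector derived from a hash
#' of its characters. Identical tokens always receive identical vectors, so
#' the backend satisfies the embedding-similarity contract and makes tests
#' reproducible without any model download. It carries no semantics: distinct
#' tokens get near-orthogonal vectors in expectation.
#'
#' @param dim Embedding dimension (default 16).
#' @return A backend: list with `name` and `embed(tokens) -> matrix`
#'   (one row per token).
#' @export
embedding_backend_hash <- function(dim = 16L) {
  embed_one <- function(token) {
    bytes <- utf8ToInt(enc2utf8(token))
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483563
    withr::with_seed(as.integer(h %% 2147483562) + 1L, stats::rnorm(dim))
  }
  list(
    name = sprintf("hash-%dd", dim),
    embed = function(tokens) {
      out <- t(vapply(tokens, embed_one, numeric(dim)))
      rownames(out) <- NULL
      out
    }
  )
}

#' Token-embedding similarity (greedy max-cosine matching F1)
#'
#' Implements the BERTScore contract without baseline rescaling: every
#' hypothesis token is matched to its maximum-cosine reference token
#' (precision) and vice versa (recall); the score is the F1 of the two. The
#' embedding backend is an injection point — see [embedding_backend_hash()]
#' for the deterministic offline backend used in tests.
#'
#' @param a,b Non-empty character vectors of tokens.
#' @param backend Embedding backend (list with `name` and `embed`).
#' @return Score, 1 for identical token sequences.
#' @export
embed_similarity <- function(a, b, backend = embedding_backend_hash()) {
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("embedding similarity is undefined for empty token sequences.")
  }
  emb <- tryCatch(backend$embed(unique(c(a, b))),
                  error = function(e) rlang::abort(sprintf(
                    "embedding backend '%s' failed: %s",
                    backend$name %||% "<unnamed>", conditionMessage(e))))
  rownames(emb) <- unique(c(a, b))
  norm <- sqrt(rowSums(emb^2))
  norm[norm == 0] <- 1
  emb <- emb / norm
  sim <- emb[a, , drop = FALSE] %*% t(emb[b, , drop = FALSE])
  prec <- mean(apply(sim, 1, max))
  rec <- mean(apply(sim, 2, max))
  if (prec + rec <= 0) return(0)
  2 * prec * rec / (prec + rec)
}

SIM_METRICS <- c("ter", "bleu", "rouge_l", "embed_f1")

#' Pairwise note-level similarity matrix
#'
#' Computes the chosen metric between every pair of notes. Directional
#' metrics (TER, BLEU) are averaged over both directions, giving a symmetric
#' matrix by construction. The diagonal holds the metric's self-score (0 for
#' TER, 1 otherwise). Polarity records whether larger values mean farther
#' apart (`distance`, TER) or closer (`similarity`, the rest).
#'
#' @param corpus A `note_corpus` with at least two notes.
#' @param metric One of `"ter"`, `"bleu"`, `"rouge_l"`, `"embed_f1"`.
#' @param ... Metric parameters (`max_n`, `smoothing`, `epsilon`, `beta`,
#'   `backend`).
#' @return An object of class `similarity_matrix`: list with `note_ids`,
#'   `values` (square numeric matrix), `metric`, `polarity`.
#' @export
pairwise_matrix <- function(corpus, metric = SIM_METRICS, ...) {
  metric <- match.arg(metric)
  n <- nrow(corpus)
  if (n < 2) rlang::abort("pairwise similarity needs at least 2 notes.")
  dots <- list(...)
  toks <- corpus$tokens
  empty <- vapply(toks, length, 1L) == 0
  if (any(empty)) {
    rlang::abort(sprintf("note(s) with no tokens: %s",
                         paste(corpus$note_id[empty], collapse = ", ")))
  }
  vals <- matrix(0, n, n)

  if (metric == "ter") {
    vocab <- unique(unlist(toks))
    coded <- lapply(toks, match, vocab)
    d <- cpp_edit_dist_matrix(coded)
    len <- vapply(toks, length, 1L)
    # mean of the two directional TERs: d/2 * (1/len_i + 1/len_j)
    vals <- d / 2 * outer(1 / len, 1 / len, "+")
    diag(vals) <- 0
  } else if (metric == "embed_f1") {
    backend <- dots$backend %||% embedding_backend_hash()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        vals[i, j] <- vals[j, i] <-
          embed_similarity(toks[[i]], toks[[j]], backend)
      }
    }
    diag(vals) <- 1
  } else {
    f <- function(i, j) {
      if (metric == "bleu") {
        mean(c(
          do.call(bleu, c(list(toks[[i]], toks[[j]]), dots)),
          do.call(bleu, c(list(toks[[j]], toks[[i]]), dots))
        ))
      } else {
        do.call(rouge_l, c(list(toks[[i]], toks[[j]]), dots))
      }
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        vals[i, j] <- vals[j, i] <- tryCatch(
          f(i, j),
          error = function(e) rlang::abort(sprintf(
            "metric %s failed on pair (%s, %s): %s", metric,
            corpus$note_id[i], corpus$note_id[j], conditionMessage(e))))
      }
    }
    diag(vals) <- 1
  }

  dimnames(vals) <- list(corpus$note_id, corpus$note_id)
  structure(
    list(note_ids = corpus$note_id, values = vals, metric = metric,
         polarity = if (metric == "ter") "distance" else "similarity"),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> metric=%s polarity=%s n=%d\n",
              x$metric, x$polarity, length(x$note_ids)))
  invisible(x)
}

#' Convert a similarity matrix to a distance object
#'
#' Similarity-polarity metrics are converted as `1 - score` (clipped at 0 for
#' floating-point safety); distance-polarity values are used directly.
#'
#' @param mat A `similarity_matrix`.
#' @return A `stats::dist` object.
#' @export
similarity_dist <- function(mat) {
  stopifnot(inherits(mat, "similarity_matrix"))
  v <- mat$values
  if (mat$polarity == "similarity") v <- pmax(1 - v, 0)
  stats::as.dist(v)
}

#' Ward hierarchical clustering of a note distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method `ward.D2`) on the distance form of the matrix.
#' Deterministic given the matrix.
#'
#' @param mat A `similarity_matrix` (similarities are converted via
#'   `1 - score` first).
#' @param k Optional number of flat clusters to cut at.
#' @return Object of class `ward_clustering`: list with `hclust`, `note_ids`,
#'   and `labels` (named integer vector, present when `k` given).
#' @export
ward_cluster <- function(mat, k = NULL) {
  stopifnot(inherits(mat, "similarity_matrix"))
  v <- mat$values
  if (!isSymmetric(unname(v), tol = 1e-8)) {
    rlang::abort("similarity matrix is not symmetric.")
  }
  if (mat$polarity == "similarity") v <- pmax(1 - v, 0)
  if (any(v < 0)) rlang::abort("negative distances are not allowed.")
  hc <- stats::hclust(stats::as.dist(v), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, note_ids = mat$note_ids, labels = labels,
                 metric = mat$metric),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> metric=%s n=%d%s\n", x$metric,
              length(x$note_ids),
              if (is.null(x$labels)) "" else
                sprintf(" k=%d", length(unique(x$labels)))))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' @param clustering A `ward_clustering`.
#' @return Newick string with note ids as leaf labels.
#' @export
dendrogram_newick <- function(clustering) {
  stopifnot(inherits(clustering, "ward_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy)
}

#' Export a dendrogram as a nested list (JSON-ready)
#'
#' @param clustering A `ward_clustering`.
#' @return Nested list with `leaf`/`height`/`children` fields.
#' @export
dendrogram_tree <- function(clustering) {
  stopifnot(inherits(clustering, "ward_clustering"))
  hc <- clustering$hclust
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  build(nrow(hc$merge))
}

#' Adjusted Rand index between two labelings
#'
#' Closed-form contingency computation of the chance-corrected agreement
#' between two partitions of the same items; 1 for identical partitions (up
#' to relabeling), about 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels, same length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean relative edit operations between two author groups
#'
#' For every relevant note pair, the minimal edit script (see [ter()]) is
#' computed and each operation count is divided by the reference length; the
#' summary reports the means of these ratios. Directions: with
#' `"a_as_reference"` the notes of `group_b` act as hypotheses and those of
#' `group_a` as references (operations transform hypothesis into reference),
#' `"b_as_reference"` is the reverse, and `"symmetrized"` averages the two.
#' Within-group summaries (`group_a == group_b`) use all ordered distinct
#' pairs, which makes all three directions coincide.
#'
#' @param corpus A `note_corpus`.
#' @param group_a,group_b Group labels present in `corpus$group`.
#' @param direction One of `"a_as_reference"`, `"b_as_reference"`,
#'   `"symmetrized"`.
#' @return One-row tibble with the mean relative insertions, deletions and
#'   substitutions, the direction and the pair count.
#' @export
group_edit_summary <- function(corpus, group_a, group_b,
                               direction = c("symmetrized", "a_as_reference",
                                             "b_as_reference")) {
  direction <- match.arg(direction)
  na <- group_notes(corpus, group_a)
  nb <- group_notes(corpus, group_b)
  vocab <- unique(c(unlist(na$tokens), unlist(nb$tokens)))
  ca <- lapply(na$tokens, match, vocab)
  cb <- lapply(nb$tokens, match, vocab)

  rel_ops <- function(hyp, ref) {
    r <- cpp_edit_ops(hyp, ref)
    c(ins = r[[2]], del = r[[3]], sub = r[[4]]) / length(ref)
  }

  within <- identical(group_a, group_b)
  pairs <- if (within) {
    idx <- utils::combn(length(ca), 2)
    lapply(seq_len(ncol(idx)), function(k) idx[, k])
  } else {
    unlist(lapply(seq_along(ca), function(i)
      lapply(seq_along(cb), function(j) c(i, j))), recursive = FALSE)
  }
  if (length(pairs) == 0) {
    rlang::abort("group edit summary needs at least one note pair.")
  }

  acc <- vapply(pairs, function(p) {
    x <- ca[[p[1]]]
    y <- if (within) ca[[p[2]]] else cb[[p[2]]]
    # a_as_reference: hyp from group_b (y is ref means...) -- see roxygen:
    # group_a notes are the references, group_b notes the hypotheses.
    fwd <- rel_ops(hyp = y, ref = x)   # a (x) as reference
    bwd <- rel_ops(hyp = x, ref = y)   # b (y) as reference
    if (within || direction == "symmetrized") (fwd + bwd) / 2
    else if (direction == "a_as_reference") fwd
    else bwd
  }, numeric(3))

  m <- rowMeans(acc)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    direction = if (within) "symmetrized" else direction,
    mean_rel_insertions = m[["ins"]],
    mean_rel_deletions = m[["del"]],
    mean_rel_substitutions = m[["sub"]],
    n_pairs = length(pairs)
  )
}

#' Edit-operation summary table over all group pairs
#'
#' Convenience wrapper running [group_edit_summary()] for every unordered
#' group pair in both directions plus the symmetrized form, and for every
#' group against itself.
#'
#' @param corpus A `note_corpus` with at least two groups.
#' @return Tibble, one row per (group pair, direction).
#' @export
group_edit_table <- function(corpus) {
  gs <- corpus_groups(corpus)
  rows <- list()
  for (i in seq_along(gs)) {
    for (j in i:length(gs)) {
      if (i == j) {
        if (sum(corpus$group == gs[i]) >= 2) {
          rows[[length(rows) + 1]] <-
            group_edit_summary(corpus, gs[i], gs[j], "symmetrized")
        }
      } else {
        for (dir in c("a_as_reference", "b_as_reference", "symmetrized")) {
          rows[[length(rows) + 1]] <-
            group_edit_summary(corpus, gs[i], gs[j], dir)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a similarity matrix to CSV
#'
#' @param mat A `similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(mat, path) {
  stopifnot(inherits(mat, "similarity_matrix"))
  df <- as.data.frame(mat$values)
  names(df) <- mat$note_ids
  df <- cbind(note_id = mat$note_ids, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
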
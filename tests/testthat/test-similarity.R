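test_that("TER matches hand-computed examples and conventions", {
  r <- ter(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(r$score, 0)
  expect_equal(unlist(r$ops[1:3]), c(insertions = 0, deletions = 0,
                                     substitutions = 0))
  r <- ter(c("a", "b", "c", "d"), c("a", "b", "c"))
  expect_equal(r$score, 1 / 3)
  expect_equal(r$ops$deletions, 1)
  expect_equal(r$ops$insertions, 0)
  expect_error(ter(c("a"), character(0)), "empty reference")
  # score can exceed 1
  expect_gt(ter(letters[1:10], "z")$score, 1)
})

test_that("TER edits equal an independent DP oracle and ops balance holds", {
  withr::with_seed(11, {
    for (i in 1:100) {
      hyp <- random_tokens(sample(1:8, 1))
      ref <- random_tokens(sample(1:8, 1))
      r <- ter(hyp, ref)
      total <- r$ops$insertions + r$ops$deletions + r$ops$substitutions
      expect_equal(total, oracle_edit_distance(hyp, ref))
      expect_equal(r$ops$insertions - r$ops$deletions,
                   r$ops$ref_length - r$ops$hyp_length)
    }
  })
})

test_that("BLEU matches the closed form and its edge cases", {
  expect_equal(bleu(letters[1:5], letters[1:5]), 1.0)
  expect_equal(bleu(c("a", "b"), c("x", "y"), smoothing = "none"), 0)
  # hand computation: p1 = 2/3, p2 = 1/2, BP = 1 -> sqrt(1/3)
  expect_equal(bleu(c("a", "b", "c"), c("a", "b", "d"), max_n = 2,
                    smoothing = "none"), sqrt(1 / 3))
  # brevity penalty: hyp shorter than ref
  expect_equal(bleu(c("a"), c("a", "b"), max_n = 1, smoothing = "none"),
               exp(1 - 2) * 1)
  expect_error(bleu(character(0), "a"), "empty")
})

test_that("ROUGE-L matches the LCS F-measure", {
  expect_equal(rouge_l(letters[1:4], letters[1:4]), 1.0)
  expect_equal(rouge_l(c("a", "b"), c("x", "y")), 0)
  # LCS = 2, precision 2/3, recall 1 -> F1 = 0.8
  expect_equal(rouge_l(c("a", "b", "c"), c("a", "c")), 0.8)
  expect_error(rouge_l(character(0), "a"), "empty")
  withr::with_seed(3, {
    for (i in 1:25) {
      a <- random_tokens(sample(2:8, 1))
      b <- random_tokens(sample(2:8, 1))
      lcs <- oracle_lcs(a, b)
      p <- lcs / length(a); r <- lcs / length(b)
      expected <- if (lcs == 0) 0 else 2 * p * r / (p + r)
      expect_equal(rouge_l(a, b), expected)
    }
  })
})

test_that("embedding similarity follows the greedy max-cosine contract", {
  backend <- embedding_backend_hash()
  expect_equal(embed_similarity(c("a", "b"), c("a", "b"), backend), 1,
               tolerance = 1e-12)
  # hand-set orthogonal 2-d vectors
  ortho <- list(name = "ortho", embed = function(tokens) {
    vecs <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
    vecs[tokens, , drop = FALSE]
  })
  expect_equal(embed_similarity("a", "b", ortho), 0)
  # hand trace: hyp (a, b, c) vs ref (a, b): precision mean(1, 1, 1) = 1
  # (c matches a), recall mean(1, 1) = 1 -> F1 = 1; with ref (b) only:
  # precision mean(0, 1, 0) = 1/3, recall 1 -> F1 = 0.5
  expect_equal(embed_similarity(c("a", "b", "c"), c("a", "b"), ortho), 1)
  expect_equal(embed_similarity(c("a", "b", "c"), c("b"), ortho), 0.5)
  bad <- list(name = "boom", embed = function(tokens) stop("nope"))
  expect_error(embed_similarity("a", "b", bad), "boom")
})

test_that("pairwise matrices are symmetric with the metric self-score", {
  co <- tiny_corpus()
  for (m in c("ter", "bleu", "rouge_l")) {
    sm <- pairwise_matrix(co, m)
    expect_true(isSymmetric(unname(sm$values)))
    expect_equal(unname(diag(sm$values)),
                 rep(if (m == "ter") 0 else 1, nrow(co)))
    expect_identical(sm$polarity, if (m == "ter") "distance" else "similarity")
  }
})

test_that("bidirectional TER averaging matches the hand formula", {
  co <- note_corpus(data.frame(
    note_id = c("a", "b", "c"), specialty = "other", generator = "human",
    case_id = "x",
    text = c("t1 t2", "u1 u2 u3 u4", "v1 v2 v3 v4 v5 v6 v7 v8")))
  sm <- pairwise_matrix(co, "ter")
  # disjoint vocab: edit distance = max(len_i, len_j)
  lens <- c(2, 4, 8)
  for (i in 1:2) for (j in (i + 1):3) {
    d <- max(lens[i], lens[j])
    expect_equal(sm$values[i, j], mean(c(d / lens[i], d / lens[j])))
  }
})

test_that("Ward clustering recovers trivial structure and validates input", {
  co <- note_corpus(data.frame(
    note_id = c("a1", "a2", "b1", "b2"), specialty = "other",
    generator = "human", case_id = "x",
    text = c("p q r", "p q r", "x y z w v u t s", "x y z w v u t s")))
  wc <- ward_cluster(pairwise_matrix(co, "ter"), k = 2)
  expect_equal(wc$labels[["a1"]], wc$labels[["a2"]])
  expect_equal(wc$labels[["b1"]], wc$labels[["b2"]])
  expect_false(wc$labels[["a1"]] == wc$labels[["b1"]])

  dup <- note_corpus(data.frame(
    note_id = c("d1", "d2", "d3"), specialty = "other", generator = "human",
    case_id = "x", text = "same text here"))
  wc1 <- ward_cluster(pairwise_matrix(dup, "ter"), k = 1)
  expect_equal(unname(wc1$labels), rep(1L, 3))

  bad <- pairwise_matrix(co, "ter")
  bad$values[1, 2] <- 99
  expect_error(ward_cluster(bad), "symmetric")
})

test_that("Ward labels are invariant under note permutation (ARI = 1)", {
  withr::with_seed(21, {
    tr <- default_study_truth(5)
    tr$group_sizes <- c(psychiatry_human = 8L, internal_medicine_human = 8L,
                        psychiatry_llm = 4L, internal_medicine_llm = 4L)
    co <- generate_corpus(tr)
    perm <- sample(nrow(co))
    co2 <- co[perm, ]
    l1 <- ward_cluster(pairwise_matrix(co, "ter"), k = 4)$labels
    l2 <- ward_cluster(pairwise_matrix(co2, "ter"), k = 4)$labels
    expect_equal(adjusted_rand_index(l1[co$note_id], l2[co$note_id]), 1)
  })
})

test_that("dendrogram exports carry note ids", {
  co <- tiny_corpus()
  wc <- ward_cluster(pairwise_matrix(co, "ter"))
  nwk <- dendrogram_newick(wc)
  expect_true(all(vapply(co$note_id, grepl, logical(1), x = nwk, fixed = TRUE)))
  tree <- dendrogram_tree(wc)
  leaves <- unlist(tree)
  expect_setequal(leaves[grepl("^(p|i)", leaves)], co$note_id)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  })
  expect_equal(adjusted_rand_index(1:5, c(2, 1, 4, 5, 3)), 1)
})

test_that("group edit summaries match the hand-built superset example", {
  co <- note_corpus(data.frame(
    note_id = c("s1", "s2", "l1", "l2"),
    specialty = c("other", "other", "other", "other"),
    generator = c("human", "human", "llm", "llm"),
    case_id = "x",
    text = c("t1 t2 t3 t4 t5", "t1 t2 t3 t4 t5",
             paste(c(paste0("t", 1:5), paste0("x", 1:10)), collapse = " "),
             paste(c(paste0("t", 1:5), paste0("x", 1:10)), collapse = " "))))
  # long notes as hypotheses, short notes as references: 10 deletions / 5
  s <- group_edit_summary(co, "other_human", "other_llm", "a_as_reference")
  expect_equal(s$mean_rel_deletions, 2.0)
  expect_equal(s$mean_rel_insertions, 0)
  fwd <- group_edit_summary(co, "other_human", "other_llm", "a_as_reference")
  bwd <- group_edit_summary(co, "other_human", "other_llm", "b_as_reference")
  sym <- group_edit_summary(co, "other_human", "other_llm", "symmetrized")
  for (col in c("mean_rel_insertions", "mean_rel_deletions",
                "mean_rel_substitutions")) {
    expect_equal(sym[[col]], (fwd[[col]] + bwd[[col]]) / 2)
  }
  # identical notes within a group: no edits
  w <- group_edit_summary(co, "other_human", "other_human")
  expect_equal(w$mean_rel_insertions + w$mean_rel_deletions +
                 w$mean_rel_substitutions, 0)
})
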
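make_docs_corpus <- function(texts, specialty = "other") {
  note_corpus(data.frame(
    note_id = paste0("n", seq_along(texts)), specialty = specialty,
    generator = "human", case_id = "x", text = texts,
    stringsAsFactors = FALSE))
}

test_that("the raw-count formula matches hand computation", {
  co <- make_docs_corpus(c("a a b", "b c"))
  model <- fit_tfidf(co)
  s1 <- chartstyle:::tfidf_scores(model, co$tokens[[1]])
  expect_equal(unname(s1["a"]), 2 * log(2 / 1))
  # ubiquitous term scores exactly 0
  expect_equal(unname(s1["b"]), 0)
  s2 <- chartstyle:::tfidf_scores(model, co$tokens[[2]])
  expect_equal(unname(s2["c"]), log(2))
  # configurable log base
  m10 <- fit_tfidf(co, log_base = 10)
  expect_equal(unname(chartstyle:::tfidf_scores(m10, co$tokens[[1]])["a"]),
               2 * log10(2))
})

test_that("document frequencies are order-invariant", {
  texts <- c("a a b", "b c", "c d a")
  m1 <- fit_tfidf(make_docs_corpus(texts))
  m2 <- fit_tfidf(make_docs_corpus(rev(texts)))
  expect_identical(m1$doc_freq, m2$doc_freq)
  expect_identical(m1$n_docs, m2$n_docs)
})

test_that("scores increase as document frequency falls at fixed term frequency", {
  co3 <- make_docs_corpus(c("a b", "a b", "a c"))  # DF(a)=3, DF(b)=2, DF(c)=1
  m <- fit_tfidf(co3)
  s <- chartstyle:::tfidf_scores(m, c("a", "b", "c"))
  expect_true(s[["a"]] < s[["b"]])
  expect_true(s[["b"]] < s[["c"]])
})

test_that("smoothed library variant L2-normalizes document vectors", {
  co <- make_docs_corpus(c("a a b", "b c"))
  m <- fit_tfidf(co, variant = "smoothed_library")
  s <- chartstyle:::tfidf_scores(m, co$tokens[[1]])
  expect_equal(sqrt(sum(s^2)), 1)
  expect_gt(s[["b"]], 0)  # smoothing keeps ubiquitous terms nonzero
})

test_that("group profiles average member documents under the shared model", {
  co <- note_corpus(data.frame(
    note_id = c("a1", "a2", "b1"),
    specialty = c("psychiatry", "psychiatry", "internal_medicine"),
    generator = "human", case_id = "x",
    text = c("a a b", "a b c", "d e")))
  model <- fit_tfidf(co)
  pa <- group_profile(model, co, "psychiatry_human", k = 3)
  manual <- (chartstyle:::tfidf_scores(model, co$tokens[[1]]) +
             chartstyle:::tfidf_scores(model, co$tokens[[2]])) / 2
  expect_equal(pa$scores, manual)
  pb <- group_profile(model, co, "internal_medicine_human", k = 3)
  expect_equal(pb$scores,
               chartstyle:::tfidf_scores(model, co$tokens[[3]]))
  # shared vocabulary across every profile from one model
  expect_identical(names(pa$scores), names(pb$scores))
  expect_error(group_profile(model, co, "nope"), "unknown")
})

test_that("top-k ranking is descending with lexicographic tie-break", {
  co <- make_docs_corpus(c("b a", "c"))
  model <- fit_tfidf(co)
  p <- group_profile(model, co, "other_human", k = 10)
  expect_equal(p$top_k$mean_tfidf, sort(p$top_k$mean_tfidf, decreasing = TRUE))
  tied <- p$top_k$term[p$top_k$mean_tfidf == max(p$top_k$mean_tfidf)]
  expect_identical(tied, sort(tied))
})

test_that("group marker tokens surface in that group's top terms", {
  withr::with_seed(14, {
    tr <- default_study_truth(14)
    tr$group_sizes <- c(psychiatry_human = 10L, internal_medicine_human = 10L,
                        psychiatry_llm = 4L, internal_medicine_llm = 4L)
    co <- generate_corpus(tr)
    model <- fit_tfidf(co)
    top3 <- group_profile(model, co, "psychiatry_human", k = 3)$top_k$term
    expect_true("psychotherapy" %in% top3)
  })
})

test_that("token filter merges multiword expressions then drops the stoplist", {
  f <- token_filter(stoplist = "the",
                    merge_expressions = c("depressive state",
                                          "major depressive disorder"))
  out <- chartstyle:::apply_token_filter(
    c("the", "major", "depressive", "disorder", "and", "depressive",
      "state", "the"), f)
  expect_identical(out, c("major_depressive_disorder", "and",
                          "depressive_state"))
  co <- make_docs_corpus(c("the the", "the"))
  expect_error(fit_tfidf(co, filter = token_filter(stoplist = "the")),
               "empty")
})
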
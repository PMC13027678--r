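small_truth <- function(seed = 3, sizes = c(psychiatry_human = 12L,
                                            internal_medicine_human = 12L,
                                            psychiatry_llm = 4L,
                                            internal_medicine_llm = 4L)) {
  tr <- default_study_truth(seed)
  tr$group_sizes <- sizes
  tr
}

test_that("the default truth reproduces the study's group structure", {
  tr <- default_study_truth(1)
  expect_equal(unname(tr$group_sizes),
               c(70L, 48L, 4L, 4L))
  co <- generate_corpus(tr)
  expect_equal(unname(table(co$group)[names(tr$group_sizes)]),
               unname(tr$group_sizes), ignore_attr = TRUE)
  # LLM-like groups are ~3x longer than their human counterparts
  len <- note_lengths(co)
  mean_len <- tapply(len, co$group, mean)
  expect_gt(mean_len[["psychiatry_llm"]], mean_len[["psychiatry_human"]] * 2)
  expect_gt(mean_len[["internal_medicine_llm"]],
            mean_len[["internal_medicine_human"]] * 2)
})

test_that("generation is bit-reproducible from the truth object", {
  tr <- small_truth(9)
  c1 <- generate_corpus(tr)
  c2 <- generate_corpus(tr)
  expect_identical(c1$raw_text, c2$raw_text)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(c1, p1)
  write_corpus_jsonl(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  c3 <- generate_corpus(small_truth(10))
  expect_false(identical(c1$raw_text, c3$raw_text))
})

test_that("degenerate style parameters force the expected extremes", {
  tr <- small_truth(5, sizes = c(psychiatry_human = 6L,
                                 internal_medicine_human = 1L,
                                 psychiatry_llm = 1L,
                                 internal_medicine_llm = 1L))
  tr$groups$psychiatry_human$template_pool <- 1
  tr$groups$psychiatry_human$template_reuse_p <- 1
  tr$groups$psychiatry_human$sentence_repeat_p <- 0
  tr$groups$psychiatry_human$filler_rate <- 0
  tr$groups$psychiatry_human$variant_probs <- list()
  co <- generate_corpus(tr)
  psych <- co[co$group == "psychiatry_human", ]
  for (i in seq_len(nrow(psych))) {
    sents <- psych$sentences[[i]]
    expect_true(all(vapply(sents, identical, logical(1), y = sents[[1]])))
  }

  tr2 <- small_truth(5, sizes = c(psychiatry_human = 6L,
                                  internal_medicine_human = 1L,
                                  psychiatry_llm = 1L,
                                  internal_medicine_llm = 1L))
  tr2$groups$psychiatry_human$template_reuse_p <- 0
  tr2$groups$psychiatry_human$sentence_repeat_p <- 0
  tr2$groups$psychiatry_human$vocab_size <- 5000
  tr2$groups$psychiatry_human$variant_probs <- list()
  co2 <- generate_corpus(tr2)
  ttrs <- corpus_redundancy(co2[co2$group == "psychiatry_human", ])$ttr
  # fresh Zipf-weighted sampling from a large vocabulary: high diversity,
  # though head tokens still repeat occasionally
  expect_true(all(ttrs > 0.6))
  tr3 <- tr2
  tr3$groups$psychiatry_human$vocab_size <- 110
  co3 <- generate_corpus(tr3)
  ttrs_small <- corpus_redundancy(co3[co3$group == "psychiatry_human", ])$ttr
  expect_gt(mean(ttrs), mean(ttrs_small))
})

test_that("validation rejects off-simplex variant probabilities", {
  expect_error(style_params(50, 5, 100, 3, 0.5, 0.1,
                            variant_probs = list(c1 = c(a = 0.5, b = 0.6))),
               "simplex")
  expect_error(style_params(50, 5, 100, 3, 1.5, 0.1), "probabilities")
})

test_that("realized group mean lengths recover the configured means", {
  tr <- small_truth(13, sizes = c(psychiatry_human = 40L,
                                  internal_medicine_human = 40L,
                                  psychiatry_llm = 4L,
                                  internal_medicine_llm = 4L))
  co <- generate_corpus(tr)
  len <- note_lengths(co)
  for (g in c("psychiatry_human", "internal_medicine_human")) {
    realized <- mean(len[co$group == g])
    expect_lt(abs(realized - tr$groups[[g]]$mean_len) /
                tr$groups[[g]]$mean_len, 0.10)
  }
})

test_that("more template reuse does not lower realized bigram duplication", {
  reuse_levels <- c(0.1, 0.5, 0.9)
  dup <- vapply(reuse_levels, function(p) {
    tr <- small_truth(19, sizes = c(psychiatry_human = 15L,
                                    internal_medicine_human = 1L,
                                    psychiatry_llm = 1L,
                                    internal_medicine_llm = 1L))
    tr$groups$psychiatry_human$template_reuse_p <- p
    co <- generate_corpus(tr)
    mean(corpus_redundancy(co[co$group == "psychiatry_human", ])$bigram_duplication)
  }, numeric(1))
  expect_true(all(diff(dup) >= 0))
})

test_that("variant diversity is highest for the psychiatrist-like group", {
  co <- generate_corpus(default_study_truth(31))
  tab <- variant_entropy_table(co, synthetic_variant_dictionary())
  h <- setNames(tab$entropy, tab$group)
  expect_gt(h[["psychiatry_human"]], h[["internal_medicine_human"]])
})

test_that("truth serializes to JSON alongside the corpus", {
  tr <- small_truth(2)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$groups$psychiatry_human$mean_len,
               tr$groups$psychiatry_human$mean_len)
})
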
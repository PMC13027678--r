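test_that("length descriptives match hand arithmetic in both units", {
  co <- note_corpus(data.frame(
    note_id = c("a", "b", "c"), specialty = "other", generator = "human",
    case_id = "x", text = c("w1 w2", "w1 w2 w3 w4", "w1 w2 w3 w4 w5 w6")))
  d <- describe_lengths(co, "tokens")
  expect_equal(d$mean, 4)
  expect_equal(d$median, 4)
  expect_equal(d$variance, 4)
  dc <- describe_lengths(co, "characters")
  expect_equal(dc$mean, mean(nchar(co$norm_text)))
  same <- note_corpus(data.frame(
    note_id = c("a", "b"), specialty = "other", generator = "human",
    case_id = "x", text = "w1 w2 w3"))
  expect_equal(describe_lengths(same)$variance, 0)
})

test_that("one-way ANOVA behaves at its boundary cases", {
  withr::with_seed(2, {
    g <- list(rnorm(10), rnorm(10) + 0.001, rnorm(10) - 0.001)
  })
  r <- anova_oneway(g)
  expect_true(r$p_value > 0.5)
  expect_equal(r$dof_between, 2)
  expect_equal(r$dof_within, 27)
  expect_error(anova_oneway(list(rep(1, 5), rep(1, 5))), "degenerate")
  expect_error(anova_oneway(list(1:3)), "length")
  sep <- anova_oneway(list(1:5, 101:105, 201:205))
  expect_lt(sep$p_value, 1e-10)
})

test_that("Welch and pooled t tests agree with stats::t.test", {
  a <- c(1.2, 2.3, 3.1, 4.8); b <- c(2.2, 3.3, 4.4, 5.1, 6.0)
  r <- welch_t(a, b)
  tt <- t.test(a, b)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_equal(r$p_value, tt$p.value)
  rp <- welch_t(a, b, pooled = TRUE)
  expect_equal(rp$dof, length(a) + length(b) - 2)
})

test_that("Mann-Whitney exact p equals full rank-assignment enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      # mix of tie-free and tied cases
      a <- sample(1:6, n, replace = (i %% 2 == 0))
      b <- sample(1:6, m, replace = TRUE)
      expect_equal(mann_whitney_u(a, b)$p_value, oracle_mw_exact(a, b),
                   info = sprintf("case %d", i))
    }
  })
})

test_that("tie-free exact p agrees with stats::wilcox.test", {
  withr::with_seed(23, {
    for (i in 1:15) {
      a <- sample(1:50, 5); b <- setdiff(sample(1:50, 12), a)[1:5]
      r <- mann_whitney_u(a, b)
      w <- wilcox.test(a, b, exact = TRUE)
      expect_equal(r$statistic, unname(w$statistic))
      expect_equal(r$p_value, w$p.value)
    }
  })
})

test_that("large samples use the tie-corrected normal approximation", {
  withr::with_seed(31, {
    a <- rnorm(40); b <- rnorm(45) + 0.5
    r <- mann_whitney_u(a, b)
    w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
    expect_identical(r$method, "normal_approx")
  })
})

test_that("Cliff delta equals brute-force pair counting", {
  expect_equal(cliff_delta(c(10, 11), c(1, 2)), 1)
  expect_equal(cliff_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliff_delta(c(1, 3), c(2, 2)), 0)
  withr::with_seed(12, {
    for (i in 1:25) {
      a <- sample(1:8, sample(2:6, 1), replace = TRUE)
      b <- sample(1:8, sample(2:6, 1), replace = TRUE)
      expect_equal(cliff_delta(a, b), oracle_cliff(a, b))
    }
  })
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.2, 0.9)
  # adjusted values dominate the raw ones, are capped at 1, and preserve
  # the step-up monotonicity in the sorted order
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # order equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap downsampling flags only genuinely extreme values", {
  const <- rep(5, 20)
  r <- bootstrap_downsample(const, 5, 4, B = 200, seed = 1)
  expect_false(r$outside)
  r <- bootstrap_downsample(rnorm(30), 99, 4, B = 200, seed = 1)
  expect_true(r$outside)
  expect_error(bootstrap_downsample(1:3, 1, 5, B = 200, seed = 1), "n_target")
  expect_error(bootstrap_downsample(1:10, 1, 4, B = 10, seed = 1), "at least 100")
})

test_that("bootstrap results are bit-reproducible under a fixed seed", {
  x <- rnorm(25)
  r1 <- bootstrap_downsample(x, 0.2, 4, B = 500, seed = 77)
  r2 <- bootstrap_downsample(x, 0.2, 4, B = 500, seed = 77)
  expect_identical(r1, r2)
  r3 <- bootstrap_downsample(x, 0.2, 4, B = 500, seed = 78)
  expect_false(identical(r1$lower95, r3$lower95))
  rm <- bootstrap_downsample(x, 0.2, 4, B = 500, seed = 77,
                             statistic = "median")
  expect_false(identical(r1$lower95, rm$lower95))
})
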
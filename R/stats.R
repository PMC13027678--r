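test_result <- function(test_name, statistic, dof = NA_real_, p_value,
                        effect_size = NA_real_, effect_name = NA_character_) {
  tibble::tibble(test_name = test_name, statistic = statistic, dof = dof,
                 p_value = p_value, effect_size = effect_size,
                 effect_name = effect_name)
}

#' Note-length descriptives by group
#'
#' Mean, median and sample variance of note length per author group, in
#' tokens or characters. The length unit is exposed because corpora are
#' reported in either convention.
#'
#' @param corpus A `note_corpus`.
#' @param unit `"tokens"` (default) or `"characters"`.
#' @return Tibble with `group`, `n`, `mean`, `median`, `variance`.
#' @export
describe_lengths <- function(corpus, unit = c("tokens", "characters")) {
  unit <- match.arg(unit)
  len <- note_lengths(corpus, unit)
  do.call(rbind, lapply(corpus_groups(corpus), function(g) {
    x <- len[corpus$group == g]
    tibble::tibble(group = g, n = length(x), mean = mean(x),
                   median = median(x),
                   variance = if (length(x) > 1) var(x) else 0)
  }))
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test) via `stats::oneway.test`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups).
#' @return One-row tibble (`test_result` layout) with the F statistic,
#'   degrees of freedom and p value.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0)) {
    rlang::abort("every group must be non-empty.")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    rlang::abort("degenerate input: all values identical (zero variance).")
  }
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ft <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  res <- test_result("anova_oneway", unname(ft$statistic),
                     p_value = unname(ft$p.value))
  res$dof <- NA_real_
  res$dof_between <- unname(ft$parameter[1])
  res$dof_within <- unname(ft$parameter[2])
  res
}

#' Two-sample t test (Welch by default)
#'
#' @param a,b Numeric samples.
#' @param pooled Use the pooled (equal-variance) variant instead of Welch.
#' @return One-row tibble (`test_result` layout).
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) {
    rlang::abort("degenerate input: all values identical (zero variance).")
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  test_result(if (pooled) "pooled_t" else "welch_t",
              unname(tt$statistic), dof = unname(tt$parameter),
              p_value = unname(tt$p.value))
}

# U statistic for sample a versus b: number of (x, y) pairs with x > y,
# counting ties as 1/2.
u_statistic <- function(a, b) {
  d <- outer(a, b, "-")
  sum(d > 0) + 0.5 * sum(d == 0)
}

# Exact two-sided p by enumerating which of the pooled positions belong to
# the first sample; feasible when choose(n + m, n) is small.
mw_exact_enumeration <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pool), n)
  us <- apply(idx, 2, function(ii) u_statistic(pool[ii], pool[-ii]))
  u_obs <- u_statistic(a, b)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic counted directly by pair comparison
#' (ties count 1/2). The null is exact when the smaller sample has at most 8
#' observations: via the exact Wilcoxon distribution when there are no ties,
#' and by full permutation enumeration when there are ties and the
#' enumeration is tractable (at most `max_enum` subsets). Otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Exact two-sided p values are `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` applies the `min(n, m) <= 8` rule.
#' @param max_enum Enumeration budget for the tied-exact path.
#' @return One-row tibble (`test_result` layout) with the U statistic and p
#'   value; `effect_size` carries the Cliff delta of `a` versus `b`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL, max_enum = 200000) {
  stopifnot(length(a) > 0, length(b) > 0)
  n <- length(a); m <- length(b)
  if (is.null(exact)) exact <- min(n, m) <= 8
  u <- u_statistic(a, b)
  ties <- any(duplicated(c(a, b)))
  p <- NA_real_
  method <- "normal_approx"
  if (exact) {
    if (!ties) {
      p_le <- stats::pwilcox(floor(u), n, m)
      p_ge <- 1 - stats::pwilcox(ceiling(u) - 1, n, m)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact"
    } else if (choose(n + m, n) <= max_enum) {
      p <- mw_exact_enumeration(a, b)
      method <- "exact_enumeration"
    } else {
      rlang::warn("ties with intractable enumeration: falling back to the normal approximation.")
    }
  }
  if (is.na(p)) {
    pool <- c(a, b)
    tie_tab <- table(pool)
    mu <- n * m / 2
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  res <- test_result("mann_whitney_u", u, p_value = p,
                     effect_size = cliff_delta(a, b),
                     effect_name = "cliff_delta")
  res$method <- method
  res
}

#' Cliff delta effect size
#'
#' Direct pair counting: the proportion of (x, y) pairs with x > y minus the
#' proportion with x < y, over all `length(a) * length(b)` pairs. Ranges
#' from -1 (complete separation, a below b) to 1 (a above b); 0 for
#' identical samples.
#'
#' @param a,b Non-empty numeric samples.
#' @return Numeric scalar in \[-1, 1\].
#' @export
cliff_delta <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  d <- outer(a, b, "-")
  (sum(d > 0) - sum(d < 0)) / (length(a) * length(b))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values via `stats::p.adjust(method = "BH")`, after
#' validating that all inputs lie in \[0, 1\].
#'
#' @param p_values Numeric vector of p values.
#' @return Adjusted p values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Bootstrap downsampling sensitivity analysis
#'
#' Tests whether an observed group-level value could be explained by the
#' small size of that group alone: the larger reference group is repeatedly
#' downsampled (without replacement, by default) to `n_target` observations,
#' the summary statistic of each resample is collected, and the observed
#' value is flagged when it falls outside the empirical 95% range
#' (2.5th-97.5th percentiles) of the resampled distribution.
#'
#' @param reference_values Numeric vector (the large group's per-note
#'   values); length must be at least `n_target`.
#' @param observed Observed value of the comparison group's statistic.
#' @param n_target Resample size (the small group's size, e.g. 4).
#' @param B Number of resamples (>= 100; default 1000).
#' @param seed Integer RNG seed; results are bit-reproducible for a fixed
#'   seed.
#' @param statistic `"mean"` (default) or `"median"` per resample.
#' @param replace Resample with replacement instead of subsampling.
#' @param metric_name Label carried into the result.
#' @return One-row tibble with `metric_name`, `n_target`, `n_replicates`,
#'   `lower95`, `upper95`, `observed`, `outside`, `seed`.
#' @export
bootstrap_downsample <- function(reference_values, observed, n_target,
                                 B = 1000L, seed = 1L,
                                 statistic = c("mean", "median"),
                                 replace = FALSE, metric_name = "value") {
  statistic <- match.arg(statistic)
  if (B < 100) rlang::abort("B must be at least 100.")
  if (n_target < 1 || n_target > length(reference_values)) {
    rlang::abort("n_target must be between 1 and length(reference_values).")
  }
  stat_fn <- if (statistic == "mean") mean else median
  stats_out <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(i)
      stat_fn(sample(reference_values, n_target, replace = replace)),
      numeric(1))
  })
  qs <- unname(quantile(stats_out, c(0.025, 0.975)))
  tibble::tibble(
    metric_name = metric_name, n_target = as.integer(n_target),
    n_replicates = as.integer(B), lower95 = qs[1], upper95 = qs[2],
    observed = observed,
    outside = observed < qs[1] | observed > qs[2],
    seed = as.integer(seed))
}
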
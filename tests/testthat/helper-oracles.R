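# Independent oracles, coded from scratch against the textbook definitions
# rather than the package's implementations.

# Brute-force word-level edit distance by plain recursion with memoisation.
oracle_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- min(
      rec(i - 1, j - 1) + (a[i] != b[j]),
      rec(i - 1, j) + 1,
      rec(i, j - 1) + 1
    )
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Longest common subsequence length by recursion.
oracle_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a[i] == b[j]) rec(i - 1, j - 1) + 1
           else max(rec(i - 1, j), rec(i, j - 1))
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Exact two-sided Mann-Whitney p by enumerating rank assignments: midranks of
# the pooled sample, rank-sum W for each subset, U = W - n(n+1)/2.
oracle_mw_exact <- function(a, b) {
  n <- length(a)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(length(pool), n)
  us <- apply(sets, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Cliff delta by explicit double loop.
oracle_cliff <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# Small hand-built corpus used across tests.
tiny_corpus <- function() {
  note_corpus(data.frame(
    note_id = c("p1", "p2", "i1", "i2"),
    specialty = c("psychiatry", "psychiatry",
                  "internal_medicine", "internal_medicine"),
    generator = c("human", "human", "human", "llm"),
    case_id = "case1",
    text = c("mood low. sleep poor. plan therapy.",
             "mood flat. sleep poor. plan therapy.",
             "bp stable. labs normal. plan statin.",
             "bp stable. bp stable. labs normal. labs normal."),
    stringsAsFactors = FALSE
  ))
}

random_tokens <- function(len, alphabet = letters[1:4]) {
  sample(alphabet, len, replace = TRUE)
}
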
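#include <Rcpp.h>
#include <zlib.h>
using namespace Rcpp;

// Word-level edit operations transforming `hyp` into `ref` under unit costs
// (no shift/reorder operation). Backtrace tie-break: match/substitution is
// preferred over deletion (of a hyp token), which is preferred over insertion
// (of a ref token), so the operation counts are canonical.
// Returns c(distance, insertions, deletions, substitutions).
// [[Rcpp::export]]
IntegerVector cpp_edit_ops(IntegerVector hyp, IntegerVector ref) {
  int n = hyp.size(), m = ref.size();
  IntegerMatrix d(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) d(i, 0) = i;
  for (int j = 0; j <= m; ++j) d(0, j) = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = d(i - 1, j - 1) + (hyp[i - 1] == ref[j - 1] ? 0 : 1);
      int del = d(i - 1, j) + 1;
      int ins = d(i, j - 1) + 1;
      d(i, j) = std::min(sub, std::min(del, ins));
    }
  }
  int ins = 0, del = 0, sub = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        d(i, j) == d(i - 1, j - 1) + (hyp[i - 1] == ref[j - 1] ? 0 : 1)) {
      if (hyp[i - 1] != ref[j - 1]) ++sub;
      --i; --j;
    } else if (i > 0 && d(i, j) == d(i - 1, j) + 1) {
      ++del; --i;
    } else {
      ++ins; --j;
    }
  }
  return IntegerVector::create(d(n, m), ins, del, sub);
}

// Symmetric matrix of word-level edit distances over a list of integer-coded
// token sequences (two-row DP, no backtrace).
// [[Rcpp::export]]
IntegerMatrix cpp_edit_dist_matrix(List docs) {
  int n = docs.size();
  std::vector<std::vector<int> > seqs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = docs[i];
    seqs[i] = std::vector<int>(v.begin(), v.end());
  }
  IntegerMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      const std::vector<int>& x = seqs[a];
      const std::vector<int>& y = seqs[b];
      int nx = x.size(), ny = y.size();
      std::vector<int> prev(ny + 1), cur(ny + 1);
      for (int j = 0; j <= ny; ++j) prev[j] = j;
      for (int i = 1; i <= nx; ++i) {
        cur[0] = i;
        for (int j = 1; j <= ny; ++j) {
          int s = prev[j - 1] + (x[i - 1] == y[j - 1] ? 0 : 1);
          int d = prev[j] + 1;
          int in = cur[j - 1] + 1;
          cur[j] = std::min(s, std::min(d, in));
        }
        std::swap(prev, cur);
      }
      out(a, b) = prev[ny];
      out(b, a) = prev[ny];
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Length of the longest common subsequence of two integer-coded sequences.
// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return prev[m];
}

// Collapsed Gibbs sampler for latent Dirichlet allocation. Token stream is
// given as parallel 0-based vectors (document id, word id). Uses R's RNG so
// results are reproducible under set.seed(). Returns posterior-mean style
// estimates from the final sweep's count tables.
// [[Rcpp::export]]
List cpp_lda_gibbs(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double eta, int n_iter) {
  int n_tok = doc_id.size();
  std::vector<int> z(n_tok);
  std::vector<int> ndk(n_docs * n_topics, 0);
  std::vector<int> nkw(n_topics * n_vocab, 0);
  std::vector<int> nk(n_topics, 0);
  std::vector<int> nd(n_docs, 0);
  for (int t = 0; t < n_tok; ++t) {
    int k = (int)(unif_rand() * n_topics);
    if (k >= n_topics) k = n_topics - 1;
    z[t] = k;
    ndk[doc_id[t] * n_topics + k]++;
    nkw[k * n_vocab + word_id[t]]++;
    nk[k]++;
    nd[doc_id[t]]++;
  }
  std::vector<double> p(n_topics);
  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < n_tok; ++t) {
      int d = doc_id[t], w = word_id[t], k = z[t];
      ndk[d * n_topics + k]--; nkw[k * n_vocab + w]--; nk[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < n_topics; ++kk) {
        double val = (ndk[d * n_topics + kk] + alpha) *
                     (nkw[kk * n_vocab + w] + eta) /
                     (nk[kk] + n_vocab * eta);
        p[kk] = val;
        tot += val;
      }
      double u = unif_rand() * tot, acc = 0.0;
      int knew = n_topics - 1;
      for (int kk = 0; kk < n_topics; ++kk) {
        acc += p[kk];
        if (u <= acc) { knew = kk; break; }
      }
      z[t] = knew;
      ndk[d * n_topics + knew]++; nkw[knew * n_vocab + w]++; nk[knew]++;
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix doc_topic(n_docs, n_topics);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < n_topics; ++k)
      doc_topic(d, k) = (ndk[d * n_topics + k] + alpha) /
                        (nd[d] + n_topics * alpha);
  NumericMatrix topic_word(n_topics, n_vocab);
  for (int k = 0; k < n_topics; ++k)
    for (int w = 0; w < n_vocab; ++w)
      topic_word(k, w) = (nkw[k * n_vocab + w] + eta) /
                         (nk[k] + n_vocab * eta);
  return List::create(_["doc_topic"] = doc_topic,
                      _["topic_word"] = topic_word);
}

// Size in bytes of the zlib (DEFLATE) stream for `bytes` at the given level.
// [[Rcpp::export]]
int cpp_deflate_size(RawVector bytes, int level) {
  uLong src_len = bytes.size();
  uLong bound = compressBound(src_len);
  std::vector<Bytef> dest(bound);
  uLongf dest_len = bound;
  int rc = compress2(dest.data(), &dest_len,
                     (const Bytef*)RAW(bytes), src_len, level);
  if (rc != Z_OK) stop("zlib compress2 failed (code %d)", rc);
  return (int)dest_len;
}
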
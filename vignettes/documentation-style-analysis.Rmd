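---
title: "Quantifying clinical documentation styles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clinical documentation styles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartstyle)
```

## The problem

Clinical notes describing the same case vary widely in how the information is
put on the page: how long the note is, how much phrasing is reused, how many
different words express the same clinical concept, how themes are emphasized.
When the comparison is between author *groups* — specialties, or human
physicians versus large language models prompted to write in a specialty's
style — these stylistic dimensions become measurable group contrasts.
`chartstyle` implements that measurement as a pipeline over a grouped corpus:
each note carries `specialty`, `generator` and `case_id` metadata, and the
default group key is the specialty-by-generator combination.

The pipeline makes few assumptions about the text itself. All analyses work
on token sequences produced by a pluggable tokenizer; the default splits
normalized text on whitespace, and morphological analyzers for unsegmented
scripts (Japanese MeCab/Sudachi-style) can be injected through the same
deterministic contract without changing any downstream computation.

## Text normalization and segmentation

`normalize_text()` applies Unicode NFKC (full-width compatibility forms map
to ASCII), removes a configurable punctuation set (by default the common
Japanese marks 。、・「」『』（） plus ASCII punctuation), collapses whitespace
runs and trims. The map is idempotent. Sentence segmentation splits on
periods or line breaks; because normalization deletes those very characters,
a note's sentences are computed on the NFKC/whitespace-standardized text
*before* punctuation removal, and each segment is then normalized and
tokenized. The sentence count used by the redundancy metrics is exactly the
number of non-empty segments.

## Structural similarity and edit decomposition

The translation edit rate between a hypothesis `h` and reference `r` is the
minimal number of word-level insertions, deletions and substitutions
transforming `h` into `r`, divided by `|r|`. Design choices:

* **No shift operation.** Only the three unit-cost operations enter the edit
  script, so the score is the classical Levenshtein distance normalized by
  reference length and can exceed 1.
* **Canonical decomposition.** Many minimal scripts can exist with different
  operation splits (e.g. two substitutions versus one deletion plus one
  insertion). The backtrace prefers match/substitution over deletion over
  insertion, making `(I, D, S)` reproducible. The balance
  `I − D = |r| − |h|` holds for every pair and is asserted property-style in
  the tests against an independently coded brute-force dynamic program.
* **Bidirectional averaging.** Directional metrics (TER, BLEU) are averaged
  over both directions; for TER the symmetric entry reduces to
  `d/2 · (1/|a| + 1/|b|)` with `d` the edit distance. The matrix records its
  polarity (`distance` for TER, `similarity` otherwise); similarities are
  converted to distances as `1 − score` before clustering. The conversion is
  recorded in the matrix metadata rather than hard-coded downstream.
* **Group edit summaries.** For a pair of groups, mean relative operations
  are reported with either group as reference plus a symmetrized form,
  because the direction determines whether extra material in the longer
  group's notes surfaces as deletions or insertions. Within-group summaries
  use all ordered distinct pairs, which makes the three directions coincide.

BLEU defaults to `max_n = 4` with epsilon smoothing (zero match counts
replaced by 0.1) and the sentence-level brevity penalty; the effective order
is capped at the shorter sequence so very short notes remain comparable.
ROUGE-L defaults to F1 (`beta = 1`). The embedding similarity implements
greedy max-cosine matching in both directions summarized as F1 — the
BERTScore contract without baseline rescaling — against an injected backend;
the bundled hash-seeded backend gives every distinct token a fixed
pseudo-random unit vector, which exercises the contract deterministically
and offline but carries no semantics.

Ward clustering uses `stats::hclust(method = "ward.D2")` on the distance
form of the matrix, the square-distance-consistent Ward variant. Flat labels
come from cutting the tree at `k`; agreement with ground truth is measured
by the adjusted Rand index in its closed contingency form.

## Lexical, topic and term-variation profiles

**TF-IDF.** One vectorizer is fitted over the concatenated corpus so all
groups share vocabulary and IDF weights. Two weightings are provided: the
raw formula `TF(t, d) · log(N / DF(t))` (default; natural log, base
configurable) in which a ubiquitous term scores exactly 0, and the common
library variant (`log((1+N)/(1+DF)) + 1`, L2-normalized) for comparability
with vectorizer-based analyses. The weighting variant is recorded in every
profile. The default stoplist is empty and multiword-merge rules are
user-supplied, since non-informative tokens are corpus-specific.

**Topics.** LDA is fitted by a collapsed Gibbs sampler (the inference method
is recorded in the result). Defaults: `K = 3`, `alpha = 1/K`, `eta = 0.01`,
400 sweeps. The sampler draws from R's RNG, so a fixed seed reproduces the
fit bit-identically. Document-topic and topic-word estimates are the
Dirichlet-smoothed count tables of the final sweep; each row sums to 1 by
construction. Group profiles are the arithmetic means of member documents'
topic proportions — topic mass normalized by group size — and remain on the
simplex. Tests tolerate label switching by matching topics to planted
structure via each group's dominant topic before asserting.

**Term variation.** A user-supplied dictionary maps each concept to its
surface forms; no licensed lexicon is bundled. Matching is exact substring
on normalized text, longest-form-first at each position, so a form that
prefixes a longer form is not double-counted. Counts pool all notes of a
group (occurrence counting by default; presence-per-note is an option), and
diversity is the Shannon entropy in bits with `0·log 0 = 0`. Entropy is
undefined (an error, not 0) when no form occurs.

## Redundancy metrics

Six per-note metrics, aggregated per group as mean, SD and median:

| metric | definition | degenerate case |
|---|---|---|
| `n_sentences` | segments by period/line break | — |
| `ttr` | unique tokens / total tokens | — |
| `inter_sentence_redundancy` | 1 − mean pairwise cosine distance of sentence TF-IDF vectors | 0 when < 2 sentences |
| `compression_ratio` | DEFLATE size / original size of UTF-8 normalized text | — |
| `unique_words_per_sentence` | mean per-sentence unique-token count | — |
| `bigram_duplication` | 1 − unique / total adjacent token pairs | 0 when < 2 tokens |

Sentence vectors use a TF-IDF model local to the note with the *smoothed*
IDF and L2 normalization. The smoothing is load-bearing: under the raw
formula a term present in every sentence would get weight 0, so a note made
of two identical sentences would produce zero vectors and an undefined
cosine; with smoothing it correctly yields redundancy 1. Compression uses
zlib DEFLATE at level 6 (configurable 1–9); ratios are
compressor-dependent, so only profiles computed at the same level are
comparable, and tests assert only the monotone property that repeated-block
text compresses further than length-matched random text, never exact ratios.

## Statistical layer

Two-sided tests throughout. ANOVA is the classical equal-variance F test;
the t test defaults to Welch with a pooled option. The Mann-Whitney U
statistic is counted directly over pairs (ties contribute ½). Its null is
exact when the smaller sample has ≤ 8 observations — via the exact Wilcoxon
distribution when tie-free, by full permutation enumeration when ties make
that necessary and the subset count is tractable — and otherwise uses the
normal approximation with tie and continuity correction. Exact two-sided p
values are `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`. Cliff delta is computed by
direct pair counting, which is its definition; the test suite still checks
it against a second, independently written loop. FDR correction is
Benjamini-Hochberg via `stats::p.adjust`. Note that BH adjusted *values* are
not idempotent under re-adjustment (only the induced decisions are
meaningful); the tests assert dominance, the cap at 1, sorted monotonicity
and order equivariance.

The bootstrap sensitivity analysis subsamples the reference group *without*
replacement to the comparison group's size (with-replacement is available
behind a flag): "downsampled to match the small sample size" describes
subsampling, and the statistic per resample defaults to the mean (median
optional). The observed value is flagged when outside the empirical
2.5–97.5 percentile range of `B` resample statistics. Under the null — the
observed value being the mean of an equally small sample from the same
distribution — the flag fires somewhat above the nominal 5% (the subsample
range slightly under-covers an independent draw, and B = 1000 percentile
estimates add noise); the acceptance suite verifies the rate stays within
5% ± 3% with a pooled-size (n = 118) reference.

## The synthetic corpus generator

`generate_corpus()` produces a grouped corpus from explicit per-group style
parameters; `default_study_truth()` encodes the study-shaped conditions:
four groups of 70 / 48 / 4 / 4 notes (psychiatrist-like, internist-like, and
the two LLM-like groups). The generative process per note: a target token
length from a truncated normal (floor 5); a fixed four-template opening
(groups share section conventions); then sentences drawn as verbatim
templates with probability `template_reuse_p`, repeats of the previous
sentence with probability `sentence_repeat_p`, or fresh Zipf-weighted
samples from the group vocabulary; concept mentions (surface forms drawn
from the group's variant distribution) are budgeted inside the target
length; the sentence loop stops when appending would overshoot the target
by more than stopping undershoots it, so realized group means are unbiased.

The frozen default parameters:

| group | mean_len | sd_len | vocab | pool | reuse | repeat | variant forms (entropy) |
|---|---|---|---|---|---|---|---|
| psychiatry, human | 80 | 12 | 400 | 6 | 0.75 | 0.02 | 8 (≈2.93 bits) |
| internal medicine, human | 60 | 9 | 300 | 6 | 0.78 | 0.02 | 4 (≈1.67 bits) |
| psychiatry, LLM | 240 | 40 | 160 | 4 | 0.85 | 0.15 | 6 (≈2.38 bits) |
| internal medicine, LLM | 180 | 35 | 140 | 4 | 0.88 | 0.15 | 5 (≈2.07 bits) |

Rationale: LLM-like groups are three times longer than their human
counterparts with far higher template reuse and sentence repetition and
smaller vocabularies — the qualitative contrasts the pipeline is meant to
detect. Human length SDs are modest because every note documents one of two
standardized scenarios. Each group's vocabulary is a shared 100-token common
pool plus a group-exclusive block, sampled with Zipf-like weights so the
exclusive block dominates usage; each group also carries a marker token in
its templates, giving the TF-IDF profile a known recoverable signal.

What the generator deliberately does **not** emulate: clinically plausible
narrative content, any particular LLM's output distribution, discourse
structure beyond sentence-level reuse, spelling variation, or section (SOAP)
organization. Passing the end-to-end tests therefore shows that the pipeline
recovers *these* planted stylistic contrasts at *these* separations and
sample sizes — not that any particular real-world corpus would separate as
cleanly, and real notes with weaker conventions or heavier length overlap
may well not.

## Numerical choices and degenerate inputs

* Empty reference sequences are domain errors for TER/BLEU/ROUGE-L/embedding
  similarity; an empty corpus, an unknown group or concept, and
  out-of-range p values raise validation errors naming the offender.
* Top-k rankings (TF-IDF terms, topic words) break score ties
  lexicographically, so exports are stable across platforms.
* All stochastic stages (LDA, bootstrap, generator) consume seeds
  explicitly; reports embed the seed and a configuration hash, and
  re-running a stage with the same inputs reproduces it bit-identically.
* Single-group corpora run the within-group stages and record explicit
  notices for the skipped between-group stages in the report manifest.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
study-shaped 126-note corpus (TER matrix over 7875 note pairs), the
bootstrap calibration at 500 replicates of B = 1000 resamples, and the
topic-recovery check on a 24-document planted corpus; the whole suite
completes in a few minutes on a single CPU.

## Known limitations

* TER ignores word order rearrangement (no shift operation), so reordered
  but otherwise identical notes appear maximally distant for their length.
* The bundled embedding backend validates the matching contract, not
  semantic similarity; substantive embedding analyses require injecting a
  real encoder.
* Entropy estimates from small groups (n = 4) are biased downward by
  sampling; the bootstrap sensitivity stage exists precisely to flag which
  group contrasts survive that imbalance.
* Compression ratios depend on the compressor level and text encoding and
  should never be compared across configurations.
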
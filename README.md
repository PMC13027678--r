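# chartstyle

Stylometric comparison of clinical-note documentation styles across author
groups.

When the same clinical case is documented by different authors — psychiatrists,
internists, or large language models prompted to write in either specialty's
style — the resulting notes differ systematically in length, phrasing,
repetition and vocabulary. `chartstyle` quantifies those differences for a
grouped corpus of free-text notes. It is aimed at clinical-NLP researchers who
want a reproducible, tokenizer-agnostic pipeline for documentation-style
analysis, including a seeded synthetic corpus generator for benchmarking the
whole pipeline against known ground truth.

## What it computes

**Structural similarity with edit decomposition.** The translation edit rate
between token sequences *h* (hypothesis) and *r* (reference) is

    TER(h, r) = (I + D + S) / |r|

where *I*, *D*, *S* are the insertions, deletions and substitutions of the
minimal word-level edit script transforming *h* into *r* (no shift/reorder
operation; unit costs; canonical backtrace). Directional scores are averaged
in both directions into a symmetric note-by-note distance matrix, clustered
with Ward's minimum-variance linkage. Per group pair, the mean relative edit
operations (each count divided by the reference length) are reported for both
directions and symmetrized — the directional asymmetry separates "adds
information" from "writes differently". BLEU (modified n-gram precision with
brevity penalty), ROUGE-L (LCS F-measure) and a pluggable token-embedding
similarity (greedy max-cosine matching F1, the BERTScore contract) complement
TER on the surface- and embedding-similarity axes.

**Lexical and topic profiles.** A single TF-IDF vectorizer is fitted over the
whole corpus — `TFIDF(t, d) = TF(t, d) · log(N / DF(t))` with shared
vocabulary and IDF weights — and each group is profiled by its mean per-term
score with top-k ranking. Latent Dirichlet allocation (collapsed Gibbs,
seeded) yields document-topic proportions whose group-size-normalized means
compare thematic emphasis across groups.

**Medical term variation.** Given a concept → surface-forms dictionary, the
diversity of expression for a concept within a group is the Shannon entropy

    H = − Σᵢ pᵢ log₂ pᵢ

over the relative frequencies of its surface forms (longest-match-first
substring matching on normalized text).

**Redundancy.** Six per-note metrics: sentence count, type-token ratio,
inter-sentence similarity (1 − mean pairwise cosine distance of TF-IDF
sentence vectors), DEFLATE compression ratio, unique words per sentence, and
the bigram duplication rate `1 − unique bigrams / total bigrams`.

**Statistics.** One-way ANOVA, Welch/pooled t, Mann-Whitney U with exact
small-sample null, Cliff delta by direct pair counting, Benjamini-Hochberg
FDR correction, and a bootstrap downsampling sensitivity analysis that
repeatedly subsamples the large reference group to the small group's size
and flags observed values outside the empirical 95% range.

## Worked example

A small synthetic corpus (10 notes, four author groups) ships with the
package:

```r
library(chartstyle)

corpus <- read_corpus_jsonl(system.file("extdata",
  "example_corpus_synthetic.jsonl", package = "chartstyle"))
describe_lengths(corpus)
#>                     group n  mean median variance
#> 1 internal_medicine_human 3  62.7     63     12.3
#> 2   internal_medicine_llm 2 131.0    131     72.0
#> 3        psychiatry_human 3  81.3     87    330.3
#> 4          psychiatry_llm 2 103.5    104    264.5
```

LLM-style notes are markedly longer. TER-based Ward clustering recovers all
four documentation styles:

```r
cl <- ward_cluster(pairwise_matrix(corpus, "ter"), k = 4)
table(cluster = cl$labels, group = corpus$group)
#> each cluster contains exactly one author group (10/10 notes correct)
```

Concept-variant entropy shows the psychiatrist-like group using the most
varied vocabulary for the same concept, and type-token ratios show the
LLM-like groups repeating themselves:

```r
dict <- read_variant_dictionary(system.file("extdata",
  "example_dictionary.tsv", package = "chartstyle"))
variant_entropy_table(corpus, dict)
#>            concept                   group total n_forms_observed entropy
#> 1 depressive_state internal_medicine_human     4                2   0.811
#> 2 depressive_state   internal_medicine_llm     5                4   1.922
#> 3 depressive_state        psychiatry_human     8                5   2.156
#> 4 depressive_state          psychiatry_llm     5                4   1.922

red <- group_redundancy(corpus)
red[red$metric == "ttr", c("group", "mean", "sd")]
#>                     group  mean     sd
#> 1 internal_medicine_human 0.570 0.0522
#> 2   internal_medicine_llm 0.287 0.0240
#> 3        psychiatry_human 0.555 0.0987
#> 4          psychiatry_llm 0.364 0.0384
```

The full pipeline — length tests, similarity matrices and dendrograms, edit
summaries, TF-IDF profiles, topic means, entropies, redundancy tables and
bootstrap sensitivity — runs as one call and writes a manifest-tracked
bundle:

```r
report <- analyze_corpus(corpus, analyze_config(
  seed = 1, dictionary = dict, bootstrap_n_target = 2))
write_report_bundle(report, "style_report")
```

A thin command-line wrapper with `simulate`, `analyze` and `report`
subcommands is installed at `inst/cli/chartstyle.R`.

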
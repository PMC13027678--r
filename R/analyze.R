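#' Configuration for an end-to-end analysis run
#'
#' @param metrics Similarity metrics to compute (subset of `"ter"`,
#'   `"bleu"`, `"rouge_l"`, `"embed_f1"`). The embedding metric requires an
#'   injected backend and is off by default.
#' @param k_clusters Flat clusters for the dendrogram cut (default: number
#'   of groups).
#' @param n_topics LDA topic count (default 3).
#' @param seed Seed for every stochastic stage (LDA, bootstrap).
#' @param tfidf_variant TF-IDF weighting, see [fit_tfidf()].
#' @param top_k Top terms/words per group and topic.
#' @param compressor_level DEFLATE level for redundancy profiles.
#' @param bootstrap_B,bootstrap_n_target Bootstrap downsampling parameters.
#' @param dictionary Optional [variant_dictionary()] for the term-variation
#'   stage (skipped when `NULL`).
#' @param embed_backend Optional embedding backend for `"embed_f1"`.
#' @param length_unit `"tokens"` or `"characters"`.
#' @return Object of class `run_config`.
#' @export
analyze_config <- function(metrics = "ter", k_clusters = NULL, n_topics = 3L,
                           seed = 1L, tfidf_variant = "paper_formula",
                           top_k = 10L, compressor_level = 6L,
                           bootstrap_B = 1000L, bootstrap_n_target = 4L,
                           dictionary = NULL, embed_backend = NULL,
                           length_unit = "tokens") {
  bad <- setdiff(metrics, SIM_METRICS)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")))
  }
  if ("embed_f1" %in% metrics && is.null(embed_backend)) {
    rlang::abort("metric 'embed_f1' requires an embedding backend.")
  }
  structure(list(metrics = metrics, k_clusters = k_clusters,
                 n_topics = as.integer(n_topics), seed = as.integer(seed),
                 tfidf_variant = tfidf_variant, top_k = as.integer(top_k),
                 compressor_level = as.integer(compressor_level),
                 bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_n_target = as.integer(bootstrap_n_target),
                 dictionary = dictionary, embed_backend = embed_backend,
                 length_unit = length_unit),
            class = "run_config")
}

config_hash <- function(config, corpus) {
  rlang::hash(list(
    config[setdiff(names(config), "embed_backend")],
    corpus$note_id, corpus$raw_text, corpus$group))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) rlang::abort(
    sprintf("analysis stage '%s' failed: %s", name, conditionMessage(e))))
}

#' Run the full documentation-style analysis
#'
#' Orchestrates every stage on one grouped corpus: length descriptives and
#' group tests (ANOVA over all groups, pairwise Mann-Whitney with Cliff
#' delta and BH correction), pairwise similarity matrices with Ward
#' clustering per metric, edit-operation summaries for every group pair in
#' both directions, shared-vocabulary TF-IDF group profiles, LDA topic means
#' and top words, concept-variant entropies (when a dictionary is supplied),
#' the six-metric redundancy table, and the bootstrap downsampling
#' sensitivity analysis of each redundancy metric (largest group as the
#' reference, each other group's mean as the observed value). Between-group
#' stages are skipped with a notice when the corpus has a single group.
#'
#' @param corpus A `note_corpus`.
#' @param config An [analyze_config()].
#' @return Object of class `style_report`: a list of stage results plus a
#'   `manifest` with the config hash, seed and skipped-stage notices.
#' @export
analyze_corpus <- function(corpus, config = analyze_config()) {
  stopifnot(inherits(corpus, "note_corpus"), inherits(config, "run_config"))
  groups <- corpus_groups(corpus)
  multi_group <- length(groups) >= 2
  notices <- character(0)
  res <- list()

  res$lengths <- stage("describe_lengths",
                       describe_lengths(corpus, config$length_unit))

  if (multi_group) {
    len <- note_lengths(corpus, config$length_unit)
    by_group <- split(len, corpus$group)
    res$length_anova <- stage("length_anova", anova_oneway(by_group))
    pairs <- utils::combn(groups, 2)
    mw <- lapply(seq_len(ncol(pairs)), function(i) {
      r <- mann_whitney_u(by_group[[pairs[1, i]]], by_group[[pairs[2, i]]])
      cbind(tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i]), r)
    })
    mw <- do.call(rbind, mw)
    mw$p_adjusted <- bh_fdr(mw$p_value)
    res$length_tests <- mw
  } else {
    notices <- c(notices, "single group: between-group length tests skipped")
  }

  if (nrow(corpus) >= 2) {
    res$similarity <- list()
    res$clustering <- list()
    k <- config$k_clusters %||% max(2L, length(groups))
    for (m in config$metrics) {
      sm <- stage(paste0("pairwise_", m), if (m == "embed_f1") {
        pairwise_matrix(corpus, m, backend = config$embed_backend)
      } else {
        pairwise_matrix(corpus, m)
      })
      res$similarity[[m]] <- sm
      res$clustering[[m]] <- stage(paste0("ward_", m),
                                   ward_cluster(sm, k = min(k, nrow(corpus))))
    }
  } else {
    notices <- c(notices, "fewer than 2 notes: similarity stages skipped")
  }

  if (multi_group) {
    res$edit_summary <- stage("group_edit_summary", group_edit_table(corpus))
  } else {
    notices <- c(notices, "single group: edit summaries limited")
    res$edit_summary <- if (nrow(corpus) >= 2) {
      group_edit_summary(corpus, groups[1], groups[1])
    } else NULL
  }

  tfidf <- stage("tfidf", fit_tfidf(corpus, config$tfidf_variant))
  res$tfidf_profiles <- stage("tfidf_profiles",
                              group_profile_table(tfidf, corpus, config$top_k))

  if (nrow(corpus) >= config$n_topics) {
    tm <- stage("topics", fit_topics(corpus, K = config$n_topics,
                                     seed = config$seed))
    res$topic_means <- stage("topic_means", group_topic_means(tm, corpus))
    res$topic_words <- do.call(rbind, lapply(seq_len(tm$n_topics), function(t)
      cbind(topic = t, topic_top_words(tm, t, config$top_k))))
  } else {
    notices <- c(notices, "fewer documents than topics: topic stage skipped")
  }

  if (!is.null(config$dictionary)) {
    res$variant_entropy <- stage("variant_entropy",
                                 variant_entropy_table(corpus, config$dictionary))
  }

  res$redundancy <- stage("redundancy",
                          group_redundancy(corpus, config$compressor_level))
  res$redundancy_notes <- stage("redundancy_notes",
                                corpus_redundancy(corpus, config$compressor_level))

  if (multi_group) {
    sizes <- table(corpus$group)
    ref_group <- names(sizes)[which.max(sizes)]
    others <- setdiff(groups, ref_group)
    notes <- res$redundancy_notes
    boot <- list()
    for (m in REDUNDANCY_METRICS) {
      ref_vals <- notes[[m]][notes$group == ref_group]
      if (length(ref_vals) < config$bootstrap_n_target) next
      for (g in others) {
        obs <- mean(notes[[m]][notes$group == g])
        b <- bootstrap_downsample(ref_vals, obs, config$bootstrap_n_target,
                                  B = config$bootstrap_B, seed = config$seed,
                                  metric_name = m)
        boot[[length(boot) + 1]] <- cbind(tibble::tibble(
          reference_group = ref_group, comparison_group = g), b)
      }
    }
    res$bootstrap <- do.call(rbind, boot)
  } else {
    notices <- c(notices, "single group: bootstrap sensitivity skipped")
  }

  res$manifest <- list(
    config_hash = config_hash(config, corpus),
    seed = config$seed,
    n_notes = nrow(corpus),
    groups = as.list(table(corpus$group)),
    stages = names(res),
    notices = notices
  )
  structure(res, class = "style_report")
}

#' @export
print.style_report <- function(x, ...) {
  cat(sprintf("<style_report> %d notes, stages: %s\n",
              x$manifest$n_notes,
              paste(setdiff(names(x), "manifest"), collapse = ", ")))
  if (length(x$manifest$notices)) {
    cat("notices:\n")
    for (n in x$manifest$notices) cat("  -", n, "\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One file per stage (CSV for tables, JSON/Newick for trees) plus a
#' `manifest.json` listing every artifact with the config hash and seed.
#'
#' @param report A `style_report`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "style_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  put_csv <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(as.data.frame(obj), p, row.names = FALSE)
    artifacts[[name]] <<- basename(p)
  }
  if (!is.null(report$lengths)) put_csv(report$lengths, "lengths")
  if (!is.null(report$length_anova)) put_csv(report$length_anova, "length_anova")
  if (!is.null(report$length_tests)) put_csv(report$length_tests, "length_tests")
  for (m in names(report$similarity)) {
    p <- file.path(dir, paste0("similarity_", m, ".csv"))
    write_similarity_csv(report$similarity[[m]], p)
    artifacts[[paste0("similarity_", m)]] <- basename(p)
    nw <- file.path(dir, paste0("dendrogram_", m, ".nwk"))
    writeLines(dendrogram_newick(report$clustering[[m]]), nw)
    artifacts[[paste0("dendrogram_", m)]] <- basename(nw)
    tj <- file.path(dir, paste0("dendrogram_", m, ".json"))
    jsonlite::write_json(dendrogram_tree(report$clustering[[m]]), tj,
                         auto_unbox = TRUE, digits = NA)
    artifacts[[paste0("dendrogram_tree_", m)]] <- basename(tj)
  }
  if (!is.null(report$edit_summary)) put_csv(report$edit_summary, "edit_summary")
  if (!is.null(report$tfidf_profiles)) put_csv(report$tfidf_profiles, "tfidf_profiles")
  if (!is.null(report$topic_means)) {
    df <- cbind(group = rownames(report$topic_means),
                as.data.frame(report$topic_means))
    put_csv(df, "topic_means")
  }
  if (!is.null(report$topic_words)) put_csv(report$topic_words, "topic_words")
  if (!is.null(report$variant_entropy)) put_csv(report$variant_entropy, "variant_entropy")
  if (!is.null(report$redundancy)) put_csv(report$redundancy, "redundancy_groups")
  if (!is.null(report$redundancy_notes)) put_csv(report$redundancy_notes, "redundancy_notes")
  if (!is.null(report$bootstrap)) put_csv(report$bootstrap, "bootstrap_sensitivity")
  manifest <- c(report$manifest, list(artifacts = artifacts))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Render a human-readable summary of a report
#'
#' @param report A `style_report`, or the path to a bundle directory written
#'   by [write_report_bundle()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  if (is.character(report)) {
    mp <- file.path(report, "manifest.json")
    if (!file.exists(mp)) rlang::abort(sprintf("no manifest at %s", mp))
    man <- jsonlite::fromJSON(mp)
    missing <- !file.exists(file.path(report, unlist(man$artifacts)))
    if (any(missing)) {
      rlang::abort(sprintf("manifest references missing artifact(s): %s",
                           paste(unlist(man$artifacts)[missing], collapse = ", ")))
    }
    lines <- c("# Documentation style report",
               sprintf("- notes: %d", man$n_notes),
               sprintf("- config hash: %s", man$config_hash),
               sprintf("- seed: %d", man$seed),
               "", "## Artifacts",
               sprintf("- %s: %s", names(man$artifacts), unlist(man$artifacts)))
    return(lines)
  }
  stopifnot(inherits(report, "style_report"))
  lines <- c("# Documentation style report",
             sprintf("- notes: %d", report$manifest$n_notes),
             sprintf("- seed: %d", report$manifest$seed), "")
  if (!is.null(report$lengths)) {
    lines <- c(lines, "## Note length by group",
               utils::capture.output(print(as.data.frame(report$lengths))), "")
  }
  if (!is.null(report$length_tests)) {
    sig <- report$length_tests[report$length_tests$p_adjusted < 0.05, ]
    lines <- c(lines, "## Length contrasts (BH-adjusted p < 0.05)",
               if (nrow(sig) == 0) "(none)" else
                 sprintf("- %s vs %s: U=%.1f, p_adj=%.3g, Cliff delta=%.2f",
                         sig$group_a, sig$group_b, sig$statistic,
                         sig$p_adjusted, sig$effect_size), "")
  }
  if (!is.null(report$redundancy)) {
    lines <- c(lines, "## Redundancy (group means)",
               utils::capture.output(print(as.data.frame(
                 report$redundancy[, c("group", "metric", "mean")]))), "")
  }
  if (length(report$manifest$notices)) {
    lines <- c(lines, "## Notices",
               paste0("- ", report$manifest$notices))
  }
  lines
}
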
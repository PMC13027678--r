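#' Build a concept -> surface-form variant dictionary
#'
#' A variant dictionary maps each clinical concept (e.g. "depressive state")
#' to the ordered set of surface forms judged semantically equivalent to it.
#' Forms must be unique within a concept and non-empty. The dictionary is
#' user-supplied; no licensed lexicon is bundled.
#'
#' @param concepts Named list: concept -> character vector of surface forms.
#' @return Object of class `variant_dictionary`.
#' @export
variant_dictionary <- function(concepts) {
  stopifnot(is.list(concepts), !is.null(names(concepts)),
            all(nzchar(names(concepts))))
  for (con in names(concepts)) {
    forms <- as.character(concepts[[con]])
    if (any(!nzchar(forms))) {
      rlang::abort(sprintf("concept '%s' contains an empty surface form", con))
    }
    if (anyDuplicated(forms)) {
      rlang::abort(sprintf("concept '%s' has duplicate surface forms", con))
    }
    concepts[[con]] <- forms
  }
  structure(concepts, class = "variant_dictionary")
}

#' Read a variant dictionary from TSV or JSON
#'
#' TSV: two columns `concept`, `surface_form` (header required). JSON: an
#' object mapping each concept to an array of forms. The format is inferred
#' from the file extension unless given.
#'
#' @param path Dictionary file.
#' @param format `"auto"`, `"tsv"` or `"json"`.
#' @return A `variant_dictionary`.
#' @export
read_variant_dictionary <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    variant_dictionary(jsonlite::fromJSON(path, simplifyVector = TRUE))
  } else {
    df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("concept", "surface_form") %in% names(df))) {
      rlang::abort("TSV dictionary needs columns 'concept' and 'surface_form'.")
    }
    variant_dictionary(split(df$surface_form, df$concept))
  }
}

# Greedy longest-match-first counting of surface forms in one normalized
# text. At each position the longest form matching there is taken and the
# scan resumes after it, so a form that is a prefix of a longer form is not
# double counted.
count_forms_in_text <- function(text, forms) {
  counts <- integer(length(forms))
  names(counts) <- forms
  cand <- list()
  for (f in forms) {
    loc <- stringi::stri_locate_all_fixed(text, f)[[1]]
    if (!is.na(loc[1, 1])) {
      cand[[length(cand) + 1]] <- data.frame(
        start = loc[, 1], end = loc[, 2], form = f,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(counts)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  cursor <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand$start[r] > cursor) {
      counts[cand$form[r]] <- counts[cand$form[r]] + 1L
      cursor <- cand$end[r]
    }
  }
  counts
}

#' Extract concept variant occurrences for one group
#'
#' Counts occurrences of every surface form of `concept` in the normalized
#' texts of the group's notes. Matching is exact substring with
#' longest-match-first priority at each position. `mode = "presence"` counts
#' each form at most once per note.
#'
#' @param corpus A `note_corpus`.
#' @param dict A `variant_dictionary`.
#' @param concept Concept name present in `dict`.
#' @param group Group label.
#' @param mode `"occurrence"` (default) or `"presence"`.
#' @return Object of class `variant_distribution`: list with `concept`,
#'   `group`, `counts` (named integer vector over the concept's forms),
#'   `probs`, `total`.
#' @export
extract_variants <- function(corpus, dict, concept, group,
                             mode = c("occurrence", "presence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dict, "variant_dictionary"))
  if (!concept %in% names(dict)) {
    rlang::abort(sprintf("unknown concept '%s'", concept))
  }
  notes <- group_notes(corpus, group)
  forms <- dict[[concept]]
  per_note <- lapply(notes$norm_text, count_forms_in_text, forms = forms)
  if (mode == "presence") per_note <- lapply(per_note, function(x) pmin(x, 1L))
  counts <- Reduce(`+`, per_note)
  total <- sum(counts)
  probs <- if (total > 0) counts / total else counts * 0
  structure(list(concept = concept, group = group, counts = counts,
                 probs = probs, total = total),
            class = "variant_distribution")
}

#' @export
print.variant_distribution <- function(x, ...) {
  cat(sprintf("<variant_distribution> concept=%s group=%s total=%d\n",
              x$concept, x$group, x$total))
  invisible(x)
}

#' Lexical entropy of a variant distribution
#'
#' Shannon entropy in bits, `H = -sum(p_i * log2(p_i))`, of the surface-form
#' frequency distribution; `0 * log(0)` is treated as 0. Higher values mean
#' more varied expression of the concept. Undefined (error) when no form
#' occurred at all.
#'
#' @param dist A `variant_distribution` (or a bare numeric vector of counts
#'   or probabilities).
#' @return Entropy in bits, between 0 and `log2(number of observed forms)`.
#' @export
lexical_entropy <- function(dist) {
  p <- if (inherits(dist, "variant_distribution")) {
    if (dist$total == 0) {
      rlang::abort("entropy is undefined: no surface form occurred.")
    }
    dist$probs
  } else {
    x <- as.numeric(dist)
    if (any(x < 0)) rlang::abort("negative counts are not allowed.")
    if (sum(x) == 0) rlang::abort("entropy is undefined for a zero total.")
    x / sum(x)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-(concept, group) entropy table
#'
#' @param corpus A `note_corpus`.
#' @param dict A `variant_dictionary`.
#' @param concepts Concepts to tabulate (default: all in `dict`).
#' @param mode Passed to [extract_variants()].
#' @return Tibble with `concept`, `group`, `total`, `n_forms_observed`,
#'   `entropy` (NA when a group has no occurrences).
#' @export
variant_entropy_table <- function(corpus, dict, concepts = names(dict),
                                  mode = "occurrence") {
  rows <- list()
  for (con in concepts) {
    for (g in corpus_groups(corpus)) {
      d <- extract_variants(corpus, dict, con, g, mode)
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept = con, group = g, total = d$total,
        n_forms_observed = sum(d$counts > 0),
        entropy = if (d$total > 0) lexical_entropy(d) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
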
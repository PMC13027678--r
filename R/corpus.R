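#' Default punctuation set removed during normalization
#'
#' Japanese full-width punctuation plus common ASCII punctuation. The study
#' design removes punctuation before token-level comparison; the exact set is
#' configurable because clinical corpora differ in orthography.
#'
#' @return Character vector of single characters.
#' @export
default_punctuation <- function() {
  c(
    "。", "、", "・", "「", "」", "『", "』",
    "（", "）",
    ".", ",", ";", ":", "!", "?", "(", ")", "\"", "'"
  )
}

#' Normalize free text for token-level comparison
#'
#' Applies Unicode NFKC normalization (mapping full-width characters to their
#' ASCII compatibility forms), removes every character in `punctuation`,
#' collapses runs of whitespace to single ASCII spaces and strips leading and
#' trailing whitespace. The function is idempotent and maps the empty string
#' to the empty string.
#'
#' @param raw Character vector of raw text.
#' @param punctuation Character vector of single characters to delete.
#' @return Character vector of normalized text, same length as `raw`.
#' @examples
#' normalize_text("Ａ　Ｂ")  # full-width -> "A B"
#' @export
normalize_text <- function(raw, punctuation = default_punctuation()) {
  stopifnot(is.character(raw))
  x <- stringi::stri_trans_nfkc(raw)
  if (length(punctuation) > 0) {
    # NFKC may map full-width punctuation onto ASCII forms, so normalize the
    # removal set the same way before building the character class.
    punct <- unique(unlist(strsplit(stringi::stri_trans_nfkc(punctuation), "")))
    cls <- paste0("[", paste0("\\Q", punct, "\\E", collapse = ""), "]")
    x <- stringi::stri_replace_all_regex(x, cls, "")
  }
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Split text into sentences at delimiter characters
#'
#' Segments on any of the delimiter characters (default: the Japanese full
#' stop, the ASCII period and the newline). Empty or whitespace-only segments
#' are dropped; order is preserved.
#'
#' @param text Character scalar.
#' @param delimiters Non-empty character vector of single-character delimiters.
#' @return Character vector of trimmed, non-empty segments.
#' @examples
#' segment_sentences("A。B。")
#' @export
segment_sentences <- function(text, delimiters = c("。", ".", "\n")) {
  stopifnot(is.character(text), length(text) == 1L)
  if (length(delimiters) == 0) {
    rlang::abort("`delimiters` must be non-empty.")
  }
  cls <- paste0("[", paste0("\\Q", delimiters, "\\E", collapse = ""), "]")
  parts <- stringi::stri_split_regex(text, cls)[[1]]
  parts <- stringi::stri_trim_both(parts)
  parts[nzchar(parts)]
}

#' Whitespace tokenizer
#'
#' The default tokenizer: splits normalized text on runs of whitespace.
#' Morphological analyzers (MeCab/Sudachi-style) can be supplied through the
#' same contract via [tokenizer_spec()]; all downstream analyses are
#' tokenizer-agnostic.
#'
#' @return A tokenizer specification (see [tokenizer_spec()]).
#' @export
tokenizer_whitespace <- function() {
  tokenizer_spec("whitespace", function(text) {
    if (!nzchar(text)) return(character(0))
    stringi::stri_split_regex(text, "\\s+")[[1]]
  })
}

#' Define a tokenizer
#'
#' A tokenizer maps normalized text to a character vector of tokens. The
#' mapping must be deterministic and tokens must contain no whitespace; both
#' are checked lazily when the tokenizer is applied.
#'
#' @param name Short identifying string, recorded in corpus metadata.
#' @param tokenize Function of one character scalar returning a character
#'   vector of tokens.
#' @return An object of class `tokenizer_spec`.
#' @export
tokenizer_spec <- function(name, tokenize) {
  stopifnot(is.character(name), length(name) == 1L, is.function(tokenize))
  structure(list(name = name, tokenize = tokenize), class = "tokenizer_spec")
}

apply_tokenizer <- function(tok, text) {
  out <- tok$tokenize(text)
  out <- as.character(out)
  if (any(grepl("\\s", out))) {
    rlang::abort(sprintf("tokenizer '%s' produced tokens containing whitespace", tok$name))
  }
  out[nzchar(out)]
}

SPECIALTY_LEVELS <- c("psychiatry", "internal_medicine", "other")
GENERATOR_LEVELS <- c("human", "llm")

#' Build a grouped note corpus
#'
#' Central container for a grouped collection of clinical notes. Each record
#' must carry `note_id`, `specialty` (one of `psychiatry`,
#' `internal_medicine`, `other`), `generator` (`human` or `llm`), `case_id`
#' and `text`; `model_name` is optional. Every note is normalized with
#' [normalize_text()], segmented with [segment_sentences()] (segmentation runs
#' on the NFKC/whitespace-standardized text so that sentence delimiters are
#' still present, then each sentence is normalized and tokenized) and
#' tokenized with the supplied tokenizer.
#'
#' @param data Data frame with the columns above.
#' @param tokenizer A [tokenizer_spec()]; defaults to whitespace tokenization.
#' @param group_key Character vector of metadata columns whose combination
#'   defines the author group; defaults to specialty x generator.
#' @param punctuation Punctuation set passed to [normalize_text()].
#' @param delimiters Sentence delimiters passed to [segment_sentences()].
#' @return A tibble of class `note_corpus` with list-columns `tokens` and
#'   `sentences` (token vectors per sentence) and a character column `group`.
#' @export
note_corpus <- function(data,
                        tokenizer = tokenizer_whitespace(),
                        group_key = c("specialty", "generator"),
                        punctuation = default_punctuation(),
                        delimiters = c("。", ".", "\n")) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("note_id", "specialty", "generator", "case_id", "text")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("corpus records are missing field(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (!"model_name" %in% names(data)) data$model_name <- NA_character_
  if (anyDuplicated(data$note_id)) {
    dup <- unique(data$note_id[duplicated(data$note_id)])
    rlang::abort(sprintf("duplicate note_id: %s", paste(dup, collapse = ", ")))
  }
  bad_spec <- setdiff(unique(data$specialty), SPECIALTY_LEVELS)
  if (length(bad_spec) > 0) {
    rlang::abort(sprintf("unknown specialty value(s): %s",
                         paste(bad_spec, collapse = ", ")))
  }
  bad_gen <- setdiff(unique(data$generator), GENERATOR_LEVELS)
  if (length(bad_gen) > 0) {
    rlang::abort(sprintf("unknown generator value(s): %s",
                         paste(bad_gen, collapse = ", ")))
  }
  missing_gk <- setdiff(group_key, names(data))
  if (length(missing_gk) > 0) {
    rlang::abort(sprintf("group_key column(s) not present: %s",
                         paste(missing_gk, collapse = ", ")))
  }

  raw <- as.character(data$text)
  norm <- normalize_text(raw, punctuation)
  tokens <- lapply(norm, function(x) apply_tokenizer(tokenizer, x))
  # Sentence segmentation happens before punctuation removal would erase the
  # delimiters: NFKC + whitespace standardization only, then split, then each
  # segment is fully normalized and tokenized.
  seg_source <- stringi::stri_trans_nfkc(gsub("\r\n?", "\n", raw))
  sentences <- lapply(seg_source, function(x) {
    segs <- segment_sentences(x, delimiters)
    toks <- lapply(normalize_text(segs, punctuation),
                   function(s) apply_tokenizer(tokenizer, s))
    toks[vapply(toks, length, 1L) > 0]
  })

  group <- do.call(paste, c(unname(data[group_key]), sep = "_"))

  out <- tibble::tibble(
    note_id = as.character(data$note_id),
    specialty = data$specialty,
    generator = data$generator,
    model_name = as.character(data$model_name),
    case_id = as.character(data$case_id),
    raw_text = raw,
    norm_text = norm,
    tokens = tokens,
    sentences = sentences,
    group = group
  )
  structure(out,
            class = c("note_corpus", class(out)),
            tokenizer = tokenizer$name,
            group_key = group_key,
            punctuation = punctuation,
            delimiters = delimiters)
}

#' @export
print.note_corpus <- function(x, ...) {
  grp <- table(x$group)
  cat(sprintf("<note_corpus> %d notes, %d group(s) [tokenizer: %s]\n",
              nrow(x), length(grp), attr(x, "tokenizer")))
  for (g in names(grp)) cat(sprintf("  %s: %d\n", g, grp[[g]]))
  invisible(x)
}

corpus_groups <- function(corpus) sort(unique(corpus$group))

group_notes <- function(corpus, group) {
  idx <- corpus$group == group
  if (!any(idx)) rlang::abort(sprintf("unknown or empty group '%s'", group))
  corpus[idx, , drop = FALSE]
}

#' Read a corpus from JSON Lines
#'
#' One JSON object per line with keys `note_id`, `specialty`, `generator`,
#' `model_name` (optional), `case_id`, `text`.
#'
#' @param path Path to the JSONL file.
#' @inheritParams note_corpus
#' @param ... Passed on to [note_corpus()].
#' @return A `note_corpus`.
#' @export
read_corpus_jsonl <- function(path, ...) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) rlang::abort(
                      sprintf("line %d of %s is not valid JSON: %s",
                              i, path, conditionMessage(e))))
    required <- c("note_id", "specialty", "generator", "case_id", "text")
    miss <- setdiff(required, names(rec))
    if (length(miss) > 0) {
      rlang::abort(sprintf("record %d (note_id=%s) is missing field(s): %s",
                           i, rec$note_id %||% "<unknown>",
                           paste(miss, collapse = ", ")))
    }
    tibble::tibble(
      note_id = as.character(rec$note_id),
      specialty = as.character(rec$specialty),
      generator = as.character(rec$generator),
      model_name = as.character(rec$model_name %||% NA_character_),
      case_id = as.character(rec$case_id),
      text = as.character(rec$text)
    )
  })
  note_corpus(do.call(rbind, recs), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus to JSON Lines
#'
#' @param corpus A `note_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      note_id = corpus$note_id[i],
      specialty = corpus$specialty[i],
      generator = corpus$generator[i],
      model_name = corpus$model_name[i],
      case_id = corpus$case_id[i],
      text = corpus$raw_text[i]
    ), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a manifest directory
#'
#' The manifest is a CSV with columns `note_id`, `specialty`, `generator`,
#' `model_name`, `case_id`, `file`; each `file` is a UTF-8 plain-text note,
#' resolved relative to the manifest's directory.
#'
#' @param manifest Path to the manifest CSV.
#' @param ... Passed on to [note_corpus()].
#' @return A `note_corpus`.
#' @export
read_corpus_manifest <- function(manifest, ...) {
  if (!file.exists(manifest)) rlang::abort(sprintf("no such file: %s", manifest))
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  required <- c("note_id", "specialty", "generator", "case_id", "file")
  miss <- setdiff(required, names(man))
  if (length(miss) > 0) {
    rlang::abort(sprintf("manifest is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  base <- dirname(manifest)
  paths <- file.path(base, man$file)
  absent <- !file.exists(paths)
  if (any(absent)) {
    rlang::abort(sprintf("manifest references missing file(s): %s",
                         paste(man$file[absent], collapse = ", ")))
  }
  man$text <- vapply(paths, function(p)
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    character(1))
  man$file <- NULL
  note_corpus(man, ...)
}

#' Note lengths in tokens or characters
#'
#' @param corpus A `note_corpus`.
#' @param unit `"tokens"` (default) or `"characters"` (characters of the
#'   normalized text).
#' @return Integer vector, one length per note.
#' @export
note_lengths <- function(corpus, unit = c("tokens", "characters")) {
  unit <- match.arg(unit)
  if (unit == "tokens") {
    vapply(corpus$tokens, length, integer(1))
  } else {
    stringi::stri_length(corpus$norm_text)
  }
}
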
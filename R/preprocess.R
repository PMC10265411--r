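#' Default abbreviation expansion map
#'
#' A small map of common English contractions plus the shorthand "od" for
#' "overdose", used by [clean_text()] before special characters are removed.
#' Keys that look like bare words are matched at word boundaries; keys that
#' begin with an apostrophe (contraction suffixes such as `"n't"`) are matched
#' as plain substrings. The map a production deployment would use is corpus
#' specific, so every entry here can be overridden or replaced.
#'
#' @return Named character vector mapping phrase to expansion.
#' @export
#' @examples
#' default_abbreviation_map()[["od"]]
default_abbreviation_map <- function() {
  c(
    "won't"  = "will not",
    "can't"  = "cannot",
    "n't"    = " not",
    "'re"    = " are",
    "'m"     = " am",
    "'ll"    = " will",
    "'ve"    = " have",
    "'d"     = " would",
    "od"     = "overdose"
  )
}

#' Clean a raw short text into a token sequence
#'
#' Applies the cleaning pipeline in a fixed order: lowercase, expand
#' abbreviations, remove every character outside `[a-z0-9 ]`, collapse
#' whitespace, then split on whitespace. A "word" is a whitespace-delimited
#' token of the cleaned string. The function is deterministic; an input that
#' cleans to nothing yields a zero-word document rather than an error.
#'
#' @param text Character scalar, the raw text.
#' @param doc_id Optional identifier carried through to the result.
#' @param abbreviation_map Named character vector of phrase expansions applied
#'   after lowercasing; defaults to [default_abbreviation_map()].
#' @return An object of class `cleaned_document`: a list with `doc_id`,
#'   `tokens` (character vector) and `word_count`.
#' @export
#' @examples
#' clean_text("My mom's in JAIL!!", abbreviation_map = c("'s" = " is"))
clean_text <- function(text, doc_id = NA_character_,
                       abbreviation_map = default_abbreviation_map()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  x <- tolower(text)
  if (length(abbreviation_map)) {
    keys <- names(abbreviation_map)
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (grepl("^[a-z0-9]+$", k)) {
        # bare-word key: word-boundary match so "od" does not hit "body"
        x <- gsub(paste0("\\b", k, "\\b"), abbreviation_map[[i]], x)
      } else {
        x <- gsub(k, abbreviation_map[[i]], x, fixed = TRUE)
      }
    }
  }
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  tokens <- if (nzchar(x)) strsplit(x, " ", fixed = TRUE)[[1]] else character(0)
  new_cleaned_document(doc_id, tokens)
}

new_cleaned_document <- function(doc_id, tokens) {
  structure(
    list(doc_id = doc_id, tokens = tokens, word_count = length(tokens)),
    class = "cleaned_document"
  )
}

#' @export
print.cleaned_document <- function(x, ...) {
  cat("<cleaned_document", if (!is.na(x$doc_id)) x$doc_id else "",
      "| ", x$word_count, "words>\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Clean a corpus of raw texts
#'
#' Vectorized wrapper around [clean_text()].
#'
#' @param texts Character vector of raw texts.
#' @param doc_ids Optional identifiers, recycled from `texts` names or indices.
#' @inheritParams clean_text
#' @return List of `cleaned_document` objects.
#' @export
clean_corpus <- function(texts, doc_ids = NULL,
                         abbreviation_map = default_abbreviation_map()) {
  if (is.null(doc_ids)) {
    doc_ids <- if (!is.null(names(texts))) names(texts) else
      as.character(seq_along(texts))
  }
  stopifnot(length(doc_ids) == length(texts))
  mapply(clean_text, texts, doc_ids,
         MoreArgs = list(abbreviation_map = abbreviation_map),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Drop duplicate documents
#'
#' Keeps the first occurrence of every identical token sequence, preserving
#' the order of the corpus otherwise.
#'
#' @param corpus List of `cleaned_document` objects.
#' @return Deduplicated list.
#' @export
deduplicate <- function(corpus) {
  if (!length(corpus)) return(corpus)
  keys <- vapply(corpus, function(d) paste(d$tokens, collapse = ""),
                 character(1))
  corpus[!duplicated(keys)]
}

#' Drop documents at or below a word-count threshold
#'
#' Retains exactly the documents with `word_count > min_exclusive`; the
#' default removes every document of five or fewer words, the eligibility
#' floor used throughout the pipeline.
#'
#' @param corpus List of `cleaned_document` objects.
#' @param min_exclusive Non-negative integer; documents must exceed it.
#' @return Filtered list.
#' @export
filter_short <- function(corpus, min_exclusive = 5L) {
  stopifnot(min_exclusive >= 0)
  counts <- vapply(corpus, `[[`, integer(1) + 0, "word_count")
  corpus[counts > min_exclusive]
}

#' Build a vocabulary from a corpus
#'
#' Index 0 is reserved for padding and index 1 for out-of-vocabulary tokens;
#' observed tokens get indices from 2 upward in order of first appearance.
#'
#' @param corpus List of `cleaned_document` objects.
#' @return Named integer vector mapping token to index (>= 2), with
#'   attributes `pad_index` (0) and `oov_index` (1).
#' @export
build_vocabulary <- function(corpus) {
  toks <- unique(unlist(lapply(corpus, `[[`, "tokens"), use.names = FALSE))
  vocab <- seq_along(toks) + 1L
  names(vocab) <- toks
  attr(vocab, "pad_index") <- 0L
  attr(vocab, "oov_index") <- 1L
  vocab
}

#' Pad or truncate a document to a fixed-length index sequence
#'
#' Shorter documents are right-padded with the padding index 0; longer
#' documents are truncated to their first `max_len` tokens. Tokens absent
#' from the vocabulary map to the out-of-vocabulary index 1.
#'
#' @param doc A `cleaned_document` (or bare character vector of tokens).
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param max_len Fixed output length (default 45, the longest cleaned title
#'   the classifier was designed around).
#' @return Integer vector of length `max_len`.
#' @export
pad_or_truncate <- function(doc, vocab, max_len = 45L) {
  tokens <- if (inherits(doc, "cleaned_document")) doc$tokens else doc
  idx <- unname(vocab[tokens])
  idx[is.na(idx)] <- attr(vocab, "oov_index")
  if (length(idx) >= max_len) idx[seq_len(max_len)]
  else c(idx, rep.int(attr(vocab, "pad_index"), max_len - length(idx)))
}

#' Encode a corpus as a fixed-width index matrix
#'
#' @inheritParams pad_or_truncate
#' @param corpus List of `cleaned_document` objects.
#' @return Integer matrix, one row per document, `max_len` columns.
#' @export
encode_corpus <- function(corpus, vocab, max_len = 45L) {
  out <- vapply(corpus, pad_or_truncate, integer(max_len),
                vocab = vocab, max_len = max_len)
  t(out)
}
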
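#' Construct a keyword query
#'
#' A query is satisfied by a text when (any phrase of `any_of` occurs) AND
#' (`require_all` is empty OR any phrase of it occurs) AND (`negate_group`
#' is empty OR no phrase of it occurs). Each group is an OR-list of lowercase
#' phrases; the groups are combined with AND / AND NOT.
#'
#' @param any_of Character vector of phrases (OR group); must be non-empty.
#' @param require_all Optional second OR group combined with AND.
#' @param negate_group Optional OR group combined with AND NOT.
#' @return An object of class `keyword_query`.
#' @export
keyword_query <- function(any_of, require_all = character(0),
                          negate_group = character(0)) {
  any_of <- tolower(any_of); require_all <- tolower(require_all)
  negate_group <- tolower(negate_group)
  stopifnot(length(any_of) >= 1L)
  structure(list(any_of = any_of, require_all = require_all,
                 negate_group = negate_group),
            class = "keyword_query")
}

#' The packaged keyword lists for sampling users
#'
#' Three queries target the groups compared throughout the pipeline. The
#' shared OR-list `S` holds phrases describing adversity events (abuse,
#' neglect, incarceration, substance use, overdose, parental separation).
#' The ACE query requires a first-person parent/guardian phrase AND an
#' `S` phrase; the first non-ACE query requires a parent phrase AND NOT any
#' `S` phrase; the second non-ACE query uses parenting-unrelated everyday
#' topics AND NOT `S`. Lists are read from the editable packaged file
#' `extdata/keyword_lists.json`.
#'
#' @return Named list with elements `ace`, `nonace1`, `nonace2` (each a
#'   `keyword_query`) and `s_phrases` (the shared OR-list).
#' @export
#' @examples
#' q <- ace_keyword_queries()
#' keyword_match("my mother went to jail last year", q$ace)
ace_keyword_queries <- function() {
  path <- system.file("extdata", "keyword_lists.json", package = "acenet",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path)
  list(
    ace = keyword_query(raw$parent_guardian, require_all = raw$s),
    nonace1 = keyword_query(raw$parent, negate_group = raw$s),
    nonace2 = keyword_query(raw$everyday, negate_group = raw$s),
    s_phrases = raw$s
  )
}

phrase_occurs <- function(text, phrases, word_boundary = TRUE) {
  if (!length(phrases)) return(logical(0))
  if (word_boundary) {
    vapply(phrases, function(p) {
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), "\\b"),
            text, perl = TRUE)
    }, logical(1))
  } else {
    vapply(phrases, grepl, logical(1), x = text, fixed = TRUE)
  }
}

#' Evaluate a keyword query against a text
#'
#' Matching is case-insensitive substring search per phrase; by default each
#' phrase must land on word boundaries so that e.g. "prison" does not match
#' "imprisonment". Queries are evaluated on the raw lowercased text, before
#' the cleaning pipeline.
#'
#' @param text Character scalar.
#' @param query A [keyword_query()].
#' @param word_boundary Logical; require word-boundary matches (default TRUE).
#' @return Logical scalar.
#' @export
keyword_match <- function(text, query, word_boundary = TRUE) {
  stopifnot(inherits(query, "keyword_query"), is.character(text),
            length(text) == 1L)
  x <- tolower(text)
  if (!any(phrase_occurs(x, query$any_of, word_boundary))) return(FALSE)
  if (length(query$require_all) &&
      !any(phrase_occurs(x, query$require_all, word_boundary))) return(FALSE)
  if (length(query$negate_group) &&
      any(phrase_occurs(x, query$negate_group, word_boundary))) return(FALSE)
  TRUE
}
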
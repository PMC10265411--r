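#' Per-user ACE alignment index
#'
#' The alignment index of a user is the "top 10% value" of the ACE mention
#' scores of their eligible texts: the `ceiling(0.1 n)`-th largest score
#' (default convention `"top_rank"`). With at least 10% of scores at or
#' above a level, the index is at or above that level, matching the design
#' intuition that affected users mention the experience at least 10% of the
#' time. The alternative convention `"smallest_rank"` returns the
#' `ceiling(0.9 n)`-th smallest score, one order-statistic step lower when
#' `0.1 n` is an integer. The index is undefined (`NA`) with fewer than
#' `min_n` scores.
#'
#' @param scores Numeric vector of ACE mention scores in `[0, 1]` for a
#'   user's eligible (> 5 words after cleaning) texts.
#' @param min_n Evidence floor; default 30 eligible texts.
#' @param convention `"top_rank"` (default) or `"smallest_rank"`.
#' @return The alignment index in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' alignment_index(rep(0.9, 30))           # 0.9
#' alignment_index(seq(0.01, 1, by = 0.01))
alignment_index <- function(scores, min_n = 30L,
                            convention = c("top_rank", "smallest_rank")) {
  convention <- match.arg(convention)
  stopifnot(all(scores >= 0 & scores <= 1))
  n <- length(scores)
  if (n < min_n) return(NA_real_)
  s <- sort(scores)
  if (convention == "top_rank") s[n - ceiling(0.1 * n) + 1L]
  else s[ceiling(0.9 * n)]
}

#' Categorize a user from their eligible mention scores
#'
#' A user is `ACE` when the alignment index is defined and at least 0.5
#' (inclusive); `NON_ACE` when they have at least `min_n` eligible scores
#' and every score is below 0.3; `INSUFFICIENT_DATA` with fewer than `min_n`
#' eligible scores; `INDETERMINATE` otherwise. The evidence floor applies to
#' the non-ACE label too, so near-empty accounts are never labeled.
#'
#' @inheritParams alignment_index
#' @param ace_threshold Alignment-index threshold for the ACE label
#'   (default 0.5, inclusive).
#' @param nonace_max Strict upper bound on every score for the non-ACE label
#'   (default 0.3).
#' @return Character scalar: one of `"ACE"`, `"NON_ACE"`, `"INDETERMINATE"`,
#'   `"INSUFFICIENT_DATA"`.
#' @export
categorize_user <- function(scores, min_n = 30L, ace_threshold = 0.5,
                            nonace_max = 0.3,
                            convention = c("top_rank", "smallest_rank")) {
  convention <- match.arg(convention)
  if (length(scores) < min_n) return("INSUFFICIENT_DATA")
  alpha <- alignment_index(scores, min_n, convention)
  if (alpha >= ace_threshold) return("ACE")
  if (max(scores) < nonace_max) return("NON_ACE")
  "INDETERMINATE"
}

#' Score a collection of users end to end
#'
#' For each user: keep the eligible documents (strictly more than
#' `min_words` words after cleaning), score them with the trained scorer,
#' compute the alignment index and assign a category.
#'
#' @param model A trained `ace_scorer` (see [train_classifier()]).
#' @param user_documents Named list: one element per user, each a list of
#'   `cleaned_document` objects.
#' @param min_words Eligibility floor on the cleaned word count (default 5,
#'   strict `>`).
#' @inheritParams categorize_user
#' @return data.frame with columns `user_id`, `n_eligible`, `alpha`,
#'   `category`.
#' @export
score_users <- function(model, user_documents, min_words = 5L, min_n = 30L,
                        ace_threshold = 0.5, nonace_max = 0.3) {
  stopifnot(!is.null(names(user_documents)))
  rows <- lapply(names(user_documents), function(uid) {
    docs <- filter_short(user_documents[[uid]], min_words)
    if (!length(docs)) {
      return(data.frame(user_id = uid, n_eligible = 0L, alpha = NA_real_,
                        category = "INSUFFICIENT_DATA",
                        stringsAsFactors = FALSE))
    }
    scores <- predict(model, docs)
    data.frame(user_id = uid, n_eligible = length(scores),
               alpha = alignment_index(scores, min_n),
               category = categorize_user(scores, min_n, ace_threshold,
                                          nonace_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build user profiles from precomputed scores
#'
#' Convenience path for scored JSONL/CSV input: takes per-text scores with
#' word counts and user ids, applies eligibility, and returns the same table
#' as [score_users()].
#'
#' @param df data.frame with columns `user_id`, `word_count`,
#'   `ace_mention_score`.
#' @inheritParams score_users
#' @return data.frame with `user_id`, `n_eligible`, `alpha`, `category`.
#' @export
profile_users <- function(df, min_words = 5L, min_n = 30L,
                          ace_threshold = 0.5, nonace_max = 0.3) {
  stopifnot(all(c("user_id", "word_count", "ace_mention_score") %in%
                  names(df)))
  df <- df[df$word_count > min_words, , drop = FALSE]
  ids <- unique(df$user_id)
  rows <- lapply(ids, function(uid) {
    s <- df$ace_mention_score[df$user_id == uid]
    data.frame(user_id = uid, n_eligible = length(s),
               alpha = alignment_index(s, min_n),
               category = categorize_user(s, min_n, ace_threshold,
                                          nonace_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
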
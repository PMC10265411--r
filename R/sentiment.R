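#' Classify a sentiment score
#'
#' Scores come from a pluggable external scorer and lie in `[-1, 1]`.
#' `s <= -0.05` is negative, `s >= 0.05` is positive, and the open interval
#' between is neutral; both boundaries are inclusive on their own side.
#'
#' @param s Numeric vector of sentiment scores in `[-1, 1]`.
#' @return Factor with levels `negative < neutral < positive`.
#' @export
#' @examples
#' classify_sentiment(c(-0.05, 0.049, 0.05))
classify_sentiment <- function(s) {
  if (any(is.na(s)) || any(s < -1 | s > 1))
    stop("sentiment scores must lie in [-1, 1]")
  factor(ifelse(s <= -0.05, "negative",
                ifelse(s >= 0.05, "positive", "neutral")),
         levels = c("negative", "neutral", "positive"), ordered = TRUE)
}

#' Per-user sentiment fractions
#'
#' Percentages of positive, negative and neutral texts among a user's
#' eligible texts; the three sum to 100 exactly up to floating point.
#'
#' @param s Numeric vector of sentiment scores for one user's eligible texts.
#' @return Named numeric vector `pct_positive`, `pct_negative`,
#'   `pct_neutral`.
#' @export
sentiment_profile <- function(s) {
  if (!length(s)) stop("sentiment profile is undefined for an empty list")
  cl <- classify_sentiment(s)
  n <- length(s)
  c(pct_positive = 100 * sum(cl == "positive") / n,
    pct_negative = 100 * sum(cl == "negative") / n,
    pct_neutral = 100 * sum(cl == "neutral") / n)
}

#' A deterministic lexicon sentiment scorer
#'
#' Stand-in for the external rule-based scorer used in production: scores a
#' text as the difference between positive and negative lexicon hits divided
#' by the token count, clamped to `[-1, 1]`. Useful for tests and examples;
#' not a reimplementation of any production sentiment model.
#'
#' @param positive,negative Character vectors of lexicon words.
#' @return A function mapping a character scalar to a score in `[-1, 1]`.
#' @export
lexicon_sentiment_scorer <- function(
    positive = c("good", "great", "happy", "love", "wonderful", "best"),
    negative = c("bad", "sad", "awful", "hate", "terrible", "worst")) {
  force(positive); force(negative)
  function(text) {
    toks <- clean_text(text)$tokens
    if (!length(toks)) return(0)
    max(-1, min(1, (sum(toks %in% positive) - sum(toks %in% negative)) /
                  length(toks)))
  }
}
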
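#' Construct a labeled corpus
#'
#' @param documents List of `cleaned_document` objects.
#' @param labels Integer vector of 0/1 class labels (1 = positive,
#'   ACE-associated class), one per document.
#' @return Object of class `labeled_corpus`.
#' @export
labeled_corpus <- function(documents, labels) {
  labels <- as.integer(labels)
  stopifnot(length(documents) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(documents = documents, labels = labels),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus:", length(x$labels), "documents,",
      sum(x$labels == 1L), "positive /", sum(x$labels == 0L), "negative>\n")
  invisible(x)
}

#' Downsample the majority class to balance a corpus
#'
#' The minority class is untouched; the majority class is subsampled
#' uniformly at random without replacement until both classes have the same
#' number of documents. Relative document order is preserved.
#'
#' @param corpus A [labeled_corpus()].
#' @param seed Integer seed for the subsample.
#' @return Balanced `labeled_corpus`.
#' @export
balance_classes <- function(corpus, seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  n_pos <- sum(corpus$labels == 1L)
  n_neg <- sum(corpus$labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be non-empty to balance the corpus")
  if (n_pos == n_neg) return(corpus)
  maj <- if (n_pos > n_neg) 1L else 0L
  keep_n <- min(n_pos, n_neg)
  idx_maj <- which(corpus$labels == maj)
  set.seed(seed)
  kept_maj <- sort(sample(idx_maj, keep_n))
  keep <- sort(c(which(corpus$labels != maj), kept_maj))
  labeled_corpus(corpus$documents[keep], corpus$labels[keep])
}

#' Split a corpus into train / validation / test partitions
#'
#' Stratified per class: within each class, documents are permuted with the
#' given seed and cut into the three fractions (default 72/8/20). Partitions
#' are disjoint, their union is the input, and per-class sizes are within one
#' document of the exact fractions.
#'
#' @param corpus A [labeled_corpus()].
#' @param fractions Length-3 numeric summing to 1.
#' @param seed Integer seed.
#' @return Object of class `split_corpus`: list with `train`, `validation`,
#'   `test` (each a `labeled_corpus`) and `split_seed`.
#' @export
split_corpus <- function(corpus, fractions = c(0.72, 0.08, 0.20), seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  for (cl in c(0L, 1L)) {
    n <- sum(corpus$labels == cl)
    if (any(round(fractions[1:2] * n) < 1L) ||
        n - sum(round(fractions[1:2] * n)) < 1L)
      stop("too few documents per class: every partition must be non-empty")
  }
  set.seed(seed)
  part <- integer(length(corpus$labels))
  for (cl in c(0L, 1L)) {
    idx <- which(corpus$labels == cl)
    idx <- sample(idx)
    n <- length(idx)
    n1 <- round(fractions[1] * n)
    n2 <- round(fractions[2] * n)
    part[idx[seq_len(n1)]] <- 1L
    part[idx[n1 + seq_len(n2)]] <- 2L
    part[idx[(n1 + n2 + 1):n]] <- 3L
  }
  take <- function(p) labeled_corpus(corpus$documents[part == p],
                                     corpus$labels[part == p])
  structure(list(train = take(1L), validation = take(2L), test = take(3L),
                 split_seed = seed),
            class = "split_corpus")
}

#' Apply the decision threshold to a mention score
#'
#' A text is classified as ACE-associated exactly when its score strictly
#' exceeds the threshold; a score equal to the threshold is negative.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
classify_score <- function(score, threshold = 0.5) {
  stopifnot(all(score >= 0 & score <= 1))
  as.integer(score > threshold)
}

#' Confusion counts at a fixed threshold
#'
#' @param labels True 0/1 labels.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5, strict `>`).
#' @return Object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), length(labels) > 0L)
  pred <- classify_score(scores, threshold)
  structure(list(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts TP:", x$TP, "TN:", x$TN,
      "FP:", x$FP, "FN:", x$FN, ">\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' The ROC curve traces false-positive against true-positive rates as the
#' decision threshold sweeps from 0 to 1; its area equals the rank-based
#' (pairwise concordance) statistic with half credit for ties, which is how
#' it is computed here.
#'
#' @param scores Numeric scores.
#' @param labels True 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The five classification performance measures
#'
#' Accuracy, precision, recall and F1 are computed from the confusion counts
#' at the fixed threshold; AUC is computed from the scores by threshold
#' sweep. A measure whose denominator is zero is reported as `NA` rather
#' than silently zero.
#'
#' @param cc A [confusion_counts()] object.
#' @param scores,labels Optional score/label vectors for the AUC; when
#'   omitted, `auc` is `NA`.
#' @return Object of class `classifier_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`.
#' @export
classifier_metrics <- function(cc, scores = NULL, labels = NULL) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(cc$TP, cc$TP + cc$FP)
  recall <- div(cc$TP, cc$TP + cc$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  auc <- if (is.null(scores)) NA_real_ else auc_score(scores, labels)
  structure(list(accuracy = div(cc$TP + cc$TN, n), precision = precision,
                 recall = recall, f1 = f1, auc = auc),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  v <- unlist(x)
  cat("<classifier_metrics>\n")
  for (nm in names(v)) cat(sprintf("  %-9s %s\n", nm,
                                   formatC(v[[nm]], digits = 4,
                                           format = "f")))
  invisible(x)
}

#' Evaluate a trained scorer on a labeled corpus
#'
#' Scores every document, applies the fixed threshold, and reports the
#' confusion counts and five performance measures.
#'
#' @param model A trained scorer from [train_classifier()].
#' @param corpus A [labeled_corpus()] (typically the held-out test split).
#' @param threshold Decision threshold (default 0.5).
#' @return List with `scores`, `confusion` and `metrics`.
#' @export
evaluate_classifier <- function(model, corpus, threshold = 0.5) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  scores <- predict(model, corpus$documents)
  cc <- confusion_counts(corpus$labels, scores, threshold)
  list(scores = scores, confusion = cc,
       metrics = classifier_metrics(cc, scores, corpus$labels))
}
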
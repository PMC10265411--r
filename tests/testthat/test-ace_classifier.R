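dummy_corpus <- function(n_pos, n_neg) {
  docs <- make_docs(lapply(seq_len(n_pos + n_neg), function(i)
    sprintf("tok%d_%d", i, 1:7)))
  labeled_corpus(docs, c(rep(1L, n_pos), rep(0L, n_neg)))
}

test_that("balance_classes downsamples the majority class reproducibly", {
  expect_identical(balance_classes(dummy_corpus(10, 10)),
                   balance_classes(dummy_corpus(10, 10)))

  corp <- dummy_corpus(100, 30)
  b1 <- balance_classes(corp, seed = 5)
  b2 <- balance_classes(corp, seed = 5)
  expect_equal(sum(b1$labels == 1L), 30L)
  expect_equal(sum(b1$labels == 0L), 30L)
  expect_identical(vapply(b1$documents, `[[`, character(1), "doc_id"),
                   vapply(b2$documents, `[[`, character(1), "doc_id"))

  # every minority-class document is preserved
  ids_min <- vapply(corp$documents[corp$labels == 0L], `[[`, character(1),
                    "doc_id")
  ids_b <- vapply(b1$documents[b1$labels == 0L], `[[`, character(1),
                  "doc_id")
  expect_setequal(ids_b, ids_min)

  empty <- labeled_corpus(corp$documents[corp$labels == 1L],
                          corp$labels[corp$labels == 1L])
  expect_error(balance_classes(empty), "non-empty")
})

test_that("split_corpus is stratified, disjoint, exhaustive, reproducible", {
  corp <- dummy_corpus(500, 500)
  sp <- split_corpus(corp, seed = 3)
  sizes <- vapply(list(sp$train, sp$validation, sp$test),
                  function(x) length(x$labels), integer(1))
  expect_equal(sizes, c(720L, 80L, 200L))
  for (part in list(sp$train, sp$validation, sp$test)) {
    expect_equal(sum(part$labels == 1L), sum(part$labels == 0L))
  }
  ids <- unlist(lapply(list(sp$train, sp$validation, sp$test),
                       function(x) vapply(x$documents, `[[`, character(1),
                                          "doc_id")))
  expect_equal(sort(ids),
               sort(vapply(corp$documents, `[[`, character(1), "doc_id")))
  expect_equal(anyDuplicated(ids), 0L)

  sp2 <- split_corpus(corp, seed = 3)
  expect_identical(sp, sp2)

  small <- split_corpus(dummy_corpus(4, 4), c(0.5, 0.25, 0.25), seed = 1)
  expect_equal(length(small$train$labels), 4L)
  expect_equal(length(small$validation$labels), 2L)
  expect_equal(length(small$test$labels), 2L)

  # with the default 72/8/20 fractions a tiny class leaves the validation
  # partition empty
  expect_error(split_corpus(dummy_corpus(4, 10)), "non-empty")
})

test_that("classify_score applies a strict threshold", {
  expect_equal(classify_score(c(0.51, 0.50, 0.0)), c(1L, 0L, 0L))
  expect_error(classify_score(1.2))
})

test_that("confusion counts match the hand-computed cases", {
  cc <- confusion_counts(c(1, 1, 1, 0, 0, 0),
                         c(0.9, 0.8, 0.4, 0.6, 0.2, 0.1))
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 2L, FN = 1L, FP = 1L, TN = 2L))

  perfect <- confusion_counts(rep(c(1, 0), each = 10),
                              rep(c(0.9, 0.1), each = 10))
  expect_equal(unclass(perfect)[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 10L, FP = 0L, FN = 0L))

  constant0 <- confusion_counts(rep(c(1, 0), each = 10), rep(0, 20))
  expect_equal(unclass(constant0)[c("TP", "FP", "TN", "FN")],
               list(TP = 0L, FP = 0L, TN = 10L, FN = 10L))
})

test_that("the five measures follow their formulas; zero denominators -> NA", {
  cc <- confusion_counts(rep(c(1, 0), each = 10),
                         c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2),
                           rep(0.1, 8)))
  m <- classifier_metrics(cc)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)

  all_neg <- confusion_counts(rep(c(1, 0), each = 5), rep(0, 10))
  expect_true(is.na(classifier_metrics(all_neg)$precision))

  # f1 is a harmonic mean: at most the arithmetic mean, at most max(P, R)
  set.seed(21)
  for (i in 1:25) {
    labels <- sample(c(0L, 1L), 40, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- stats::runif(40)
    m <- classifier_metrics(confusion_counts(labels, scores), scores, labels)
    if (is.na(m$f1)) next
    expect_lte(m$f1, (m$precision + m$recall) / 2 + 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("AUC equals the pairwise-concordance oracle, with ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    labels <- c(1L, 0L, sample(c(0L, 1L), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_score(scores, labels), orc_auc(scores, labels))
  }
})

test_that("accuracy is invariant under label swap plus threshold flip", {
  set.seed(41)
  for (i in 1:10) {
    labels <- sample(c(0L, 1L), 30, replace = TRUE)
    scores <- stats::runif(30)  # tie-free almost surely
    thr <- stats::runif(1, 0.2, 0.8)
    acc1 <- classifier_metrics(confusion_counts(labels, scores, thr))$accuracy
    acc2 <- classifier_metrics(
      confusion_counts(1L - labels, 1 - scores, 1 - thr))$accuracy
    expect_equal(acc1, acc2)
  }
})

test_that("the scorer learns a separable corpus and is seed-deterministic", {
  corp <- generate_corpus(corpus_spec(n_pos = 300, n_neg = 300, seed = 5))
  sp <- split_corpus(corp, seed = 6)
  cfg <- cnn_config(epochs = 10)
  model <- train_classifier(sp, cfg, seed = 9)
  ev <- evaluate_classifier(model, sp$test)
  expect_gte(ev$metrics$accuracy, 0.95)
  expect_true(all(ev$scores >= 0 & ev$scores <= 1))

  model2 <- train_classifier(sp, cfg, seed = 9)
  expect_identical(predict(model2, sp$test$documents), ev$scores)

  # all-OOV documents of equal length get identical scores
  oov1 <- acenet:::new_cleaned_document("o1", sprintf("unseen%d", 1:8))
  oov2 <- acenet:::new_cleaned_document("o2", sprintf("novel%d", 1:8))
  expect_equal(predict(model, oov1), predict(model, oov2))

  expect_error(train_classifier(
    structure(list(train = labeled_corpus(list(), integer(0)),
                   validation = sp$validation, test = sp$test),
              class = "split_corpus"), cfg), "empty training set")
})
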
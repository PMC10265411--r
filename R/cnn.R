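#' Configuration for the convolutional text scorer
#'
#' The scorer is the canonical text-convolution design: a trainable word
#' embedding, parallel convolution filters of several widths, global
#' max-pooling over positions, and a dense softmax layer. The positive-class
#' softmax output in `[0, 1]` is the ACE mention score. Training is plain
#' minibatch Adam on cross-entropy with early stopping on validation loss.
#'
#' @param embedding_dim Embedding dimension (default 16). A pretrained
#'   embedding matrix may be supplied to [train_classifier()] instead of the
#'   random initialization.
#' @param filter_widths Integer vector of convolution widths (default 3,4,5).
#' @param n_filters Filters per width (default 16).
#' @param max_len Fixed input length in tokens (default 45).
#' @param epochs Maximum training epochs (default 20).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience on validation loss (default 3).
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(embedding_dim = 16L, filter_widths = c(3L, 4L, 5L),
                       n_filters = 16L, max_len = 45L, epochs = 20L,
                       batch_size = 64L, learning_rate = 1e-3,
                       patience = 3L) {
  stopifnot(embedding_dim >= 1, all(filter_widths >= 1),
            all(filter_widths <= max_len), n_filters >= 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 filter_widths = as.integer(filter_widths),
                 n_filters = as.integer(n_filters),
                 max_len = as.integer(max_len),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience)),
            class = "cnn_config")
}

# Forward pass for one minibatch. X: n x L integer index matrix (0 = pad).
# Returns list with the quantities needed for backprop.
cnn_forward <- function(params, X, cfg) {
  n <- nrow(X); L <- ncol(X); d <- cfg$embedding_dim
  tok <- as.vector(t(X))                       # doc-major token stream
  emb <- params$E[tok + 1L, , drop = FALSE]    # (n*L) x d
  widths <- cfg$filter_widths
  Fn <- cfg$n_filters
  H <- matrix(0, n, length(widths) * Fn)
  cache <- vector("list", length(widths))
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    P <- L - w + 1L
    base <- rep((seq_len(n) - 1L) * L, each = P) + rep(seq_len(P), n)
    M <- matrix(0, n * P, w * d)
    for (k in seq_len(w)) {
      M[, ((k - 1L) * d + 1L):(k * d)] <- emb[base + (k - 1L), , drop = FALSE]
    }
    Z <- M %*% params$W[[wi]]
    Z <- sweep(Z, 2L, params$b[[wi]], `+`)
    A <- pmax(Z, 0)
    # global max pool over positions; columns of mm are (filter, doc) blocks
    mm <- matrix(A, nrow = P)                  # P x (n*Fn), filter-major
    am <- max.col(t(mm), ties.method = "first")
    pooled <- mm[cbind(am, seq_len(ncol(mm)))]
    Hw <- matrix(pooled, nrow = n, ncol = Fn)
    H[, ((wi - 1L) * Fn + 1L):(wi * Fn)] <- Hw
    cache[[wi]] <- list(M = M, base = base, P = P,
                        argmax = matrix(am, nrow = n, ncol = Fn), Hw = Hw)
  }
  logits <- sweep(H %*% params$Wd, 2L, params$bd, `+`)
  zmax <- pmax(logits[, 1L], logits[, 2L])
  ez <- exp(logits - zmax)
  probs <- ez / rowSums(ez)
  list(tok = tok, emb = emb, H = H, probs = probs, cache = cache,
       n = n, L = L)
}

# Backward pass; y is the 0/1 label vector. Returns gradients with the same
# shapes as params.
cnn_backward <- function(params, fwd, y, cfg) {
  n <- fwd$n; L <- fwd$L; d <- cfg$embedding_dim; Fn <- cfg$n_filters
  Y <- cbind(1 - y, y)
  dlogits <- (fwd$probs - Y) / n
  gWd <- crossprod(fwd$H, dlogits)
  gbd <- colSums(dlogits)
  dH <- dlogits %*% t(params$Wd)
  gE <- matrix(0, nrow(params$E), d)
  gW <- vector("list", length(cfg$filter_widths))
  gb <- vector("list", length(cfg$filter_widths))
  dembflat <- matrix(0, n * L, d)
  for (wi in seq_along(cfg$filter_widths)) {
    w <- cfg$filter_widths[wi]
    cc <- fwd$cache[[wi]]
    P <- cc$P
    dHw <- dH[, ((wi - 1L) * Fn + 1L):(wi * Fn), drop = FALSE]
    dHw[cc$Hw <= 0] <- 0                       # ReLU at the pooled maximum
    dZ <- matrix(0, n * P, Fn)
    for (f in seq_len(Fn)) {
      rows <- (seq_len(n) - 1L) * P + cc$argmax[, f]
      dZ[cbind(rows, f)] <- dHw[, f]
    }
    gW[[wi]] <- crossprod(cc$M, dZ)
    gb[[wi]] <- colSums(dZ)
    dM <- dZ %*% t(params$W[[wi]])
    for (k in seq_len(w)) {
      rows <- cc$base + (k - 1L)
      dembflat[rows, ] <- dembflat[rows, ] +
        dM[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
    }
  }
  acc <- rowsum(dembflat, group = fwd$tok)
  gE[as.integer(rownames(acc)) + 1L, ] <- acc
  gE[1L, ] <- 0                                # padding row stays fixed
  list(E = gE, W = gW, b = gb, Wd = gWd, bd = gbd)
}

adam_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (j in seq_along(params[[nm]])) {
        r <- upd(params[[nm]][[j]], grads[[nm]][[j]],
                 state$m[[nm]][[j]], state$v[[nm]][[j]])
        params[[nm]][[j]] <- r$p
        state$m[[nm]][[j]] <- r$m
        state$v[[nm]][[j]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r$p
      state$m[[nm]] <- r$m
      state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

cnn_init_params <- function(vocab_size, cfg, embedding = NULL) {
  d <- cfg$embedding_dim
  nrowE <- vocab_size + 2L                     # + pad and OOV rows
  E <- if (is.null(embedding)) {
    matrix(stats::runif(nrowE * d, -0.05, 0.05), nrowE, d)
  } else {
    stopifnot(nrow(embedding) == nrowE, ncol(embedding) == d)
    embedding
  }
  E[1L, ] <- 0                                 # padding embeds to zero
  W <- list(); b <- list()
  for (wi in seq_along(cfg$filter_widths)) {
    w <- cfg$filter_widths[wi]
    fan_in <- w * d
    W[[wi]] <- matrix(stats::rnorm(fan_in * cfg$n_filters,
                                   sd = sqrt(2 / fan_in)),
                      fan_in, cfg$n_filters)
    b[[wi]] <- rep(0, cfg$n_filters)
  }
  nh <- length(cfg$filter_widths) * cfg$n_filters
  Wd <- matrix(stats::rnorm(nh * 2L, sd = sqrt(1 / nh)), nh, 2L)
  list(E = E, W = W, b = b, Wd = Wd, bd = rep(0, 2L))
}

cnn_loss <- function(params, X, y, cfg) {
  fwd <- cnn_forward(params, X, cfg)
  p <- fwd$probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train the convolutional ACE mention scorer
#'
#' Fits the embedding + convolution + max-pool + softmax scorer on the train
#' partition, using the validation partition for early stopping (training
#' stops once validation loss has not improved for `patience` epochs, and
#' the best-validation parameters are kept). With a fixed `seed` and
#' single-threaded linear algebra the run is deterministic.
#'
#' @param split A [split_corpus()] with non-empty train partition.
#' @param config A [cnn_config()].
#' @param seed Integer training seed (weight init and minibatch order).
#' @param embedding Optional pretrained embedding matrix with
#'   `vocab size + 2` rows (row 1 = padding, row 2 = out-of-vocabulary) and
#'   `embedding_dim` columns; default is random trainable initialization.
#' @param quiet Suppress the per-epoch progress line (default TRUE).
#' @return Object of class `ace_scorer` holding the vocabulary, parameters
#'   and configuration. Use [predict.ace_scorer()] to score documents.
#' @export
train_classifier <- function(split, config = cnn_config(), seed = 1L,
                             embedding = NULL, quiet = TRUE) {
  stopifnot(inherits(split, "split_corpus"), inherits(config, "cnn_config"))
  if (!length(split$train$labels)) stop("empty training set")
  vocab <- build_vocabulary(split$train$documents)
  Xtr <- encode_corpus(split$train$documents, vocab, config$max_len)
  ytr <- split$train$labels
  has_val <- length(split$validation$labels) > 0L
  if (has_val) {
    Xva <- encode_corpus(split$validation$documents, vocab, config$max_len)
    yva <- split$validation$labels
  }
  set.seed(seed)
  params <- cnn_init_params(length(vocab), config, embedding)
  state <- adam_state(params)
  best <- list(loss = Inf, params = params)
  stall <- 0L
  n <- nrow(Xtr)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- cnn_forward(params, Xtr[idx, , drop = FALSE], config)
      grads <- cnn_backward(params, fwd, ytr[idx], config)
      res <- adam_step(params, grads, state, config$learning_rate)
      params <- res$params
      state <- res$state
    }
    vloss <- if (has_val) cnn_loss(params, Xva, yva, config)
             else cnn_loss(params, Xtr, ytr, config)
    if (!quiet)
      message(sprintf("epoch %d: validation loss %.4f", epoch, vloss))
    if (vloss < best$loss - 1e-5) {
      best <- list(loss = vloss, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(vocab = vocab, params = best$params, config = config,
                 training_seed = seed, validation_loss = best$loss),
            class = "ace_scorer")
}

#' Score documents with a trained scorer
#'
#' @param object An `ace_scorer` from [train_classifier()].
#' @param newdata List of `cleaned_document` objects (or a single one), or an
#'   already-encoded integer index matrix.
#' @param ... Unused.
#' @return Numeric vector of ACE mention scores in `[0, 1]` (softmax
#'   probability of the positive class).
#' @export
predict.ace_scorer <- function(object, newdata, ...) {
  if (inherits(newdata, "cleaned_document")) newdata <- list(newdata)
  X <- if (is.matrix(newdata)) newdata
       else encode_corpus(newdata, object$vocab, object$config$max_len)
  scores <- numeric(nrow(X))
  for (start in seq(1L, nrow(X), by = 256L)) {
    idx <- start:min(start + 255L, nrow(X))
    fwd <- cnn_forward(object$params, X[idx, , drop = FALSE], object$config)
    scores[idx] <- fwd$probs[, 2L]
  }
  scores
}

#' @export
print.ace_scorer <- function(x, ...) {
  cat("<ace_scorer:", length(x$vocab), "word vocabulary,",
      "widths", paste(x$config$filter_widths, collapse = "/"),
      "x", x$config$n_filters, "filters, seed", x$training_seed, ">\n")
  invisible(x)
}
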
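#' Save / load a trained scorer
#'
#' A trained `ace_scorer` is a plain list of numeric matrices plus the
#' vocabulary and configuration; it is archived as a single RDS file.
#'
#' @param model An `ace_scorer` from [train_classifier()].
#' @param path Destination file.
#' @return `save_scorer` returns `path` invisibly; `load_scorer` returns the
#'   restored `ace_scorer`.
#' @export
save_scorer <- function(model, path) {
  stopifnot(inherits(model, "ace_scorer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ace_scorer"))
  model
}
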
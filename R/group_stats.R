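#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Computes the U statistic for the first sample and a two-sided p-value.
#' With a combined sample of at most `exact_max` observations and no ties
#' the exact null distribution of U is used (doubling the smaller tail,
#' capped at 1); otherwise the normal approximation with tie correction and
#' a continuity correction is used.
#'
#' @param a,b Numeric vectors, both non-empty; ties allowed.
#' @param exact_max Largest combined sample size for the exact path
#'   (default 25).
#' @return List with `statistic` (U for sample `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value  # 0.1 exactly
rank_sum_test <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            !anyNA(a), !anyNA(b))
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (n1 + n2 <= exact_max && !has_ties) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    list(statistic = U, p_value = min(1, p), method = "exact")
  } else {
    N <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = U, p_value = 1,
                                 method = "normal_approximation"))
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(statistic = U, p_value = min(1, 2 * stats::pnorm(-z)),
         method = "normal_approximation")
  }
}

#' Bonferroni correction
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (default 3, the three pairwise group comparisons).
#' @return Corrected p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = 3L) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1L)
  pmin(1, m * p)
}

#' Compare a metric across the three root-user groups
#'
#' Runs the two-sided rank-sum test on each of the three unordered group
#' pairs, Bonferroni-corrects over the three comparisons, and reports
#' descriptive statistics per group. Missing metric values (`NA`, the
#' "avoided calculating" cases) are dropped per group before testing; a pair
#' with an empty side is reported with `NA` statistics while the remaining
#' pairs are still tested.
#'
#' @param values Numeric vector of metric values (may contain `NA`).
#' @param groups Vector of group labels parallel to `values`; exactly the
#'   levels `ACE`, `NON_ACE_1`, `NON_ACE_2` are compared (default taken from
#'   the data when it has three or fewer unique labels).
#' @param metric_name Optional name carried into the output.
#' @return List of class `group_comparison` with elements `metric`,
#'   `groups` (data.frame: group, n, mean, sd, median) and `pairs`
#'   (data.frame: group_a, group_b, statistic, p_raw, p_bonferroni).
#' @export
compare_groups <- function(values, groups, metric_name = "metric") {
  stopifnot(length(values) == length(groups))
  lv <- if (is.factor(groups)) levels(groups) else sort(unique(as.character(groups)))
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (sum(vapply(lv, function(g) any(groups == g), logical(1))) < 2L)
    stop("need at least 2 non-empty groups")
  desc <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  combs <- utils::combn(lv, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    ga <- combs[1L, j]; gb <- combs[2L, j]
    va <- values[groups == ga]; vb <- values[groups == gb]
    if (!length(va) || !length(vb)) {
      return(data.frame(group_a = ga, group_b = gb, statistic = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    ts <- rank_sum_test(va, vb)
    data.frame(group_a = ga, group_b = gb, statistic = ts$statistic,
               p_raw = ts$p_value, stringsAsFactors = FALSE)
  }))
  pairs$p_bonferroni <- bonferroni(pairs$p_raw, m = 3L)
  structure(list(metric = metric_name, groups = desc, pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$metric, "\n\n")
  print(x$groups, row.names = FALSE)
  cat("\nPairwise two-sided rank-sum tests (Bonferroni m = 3):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
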
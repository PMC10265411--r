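#' Construct a sampled directed egocentric follow network
#'
#' Nodes are the root plus its sampled followers and followees; each edge
#' `(a, b)` means a follows b. Every follower must have an edge to the root
#' and the root must have an edge to every followee; edges among sampled
#' neighbors are taken as given (a missing edge means "no edge" — partial
#' observation is the caller's responsibility). `k_in`/`k_out` carry the
#' root's total follower/followee counts before sampling.
#'
#' @param root Root user id (character scalar).
#' @param followers Character vector of sampled follower ids.
#' @param followees Character vector of sampled followee ids (may overlap
#'   with `followers`: reciprocal neighbors appear in both).
#' @param edges Two-column matrix or data.frame of (source, target) ids.
#' @param k_in,k_out Total degree counts; default to the sampled counts.
#' @return Object of class `ego_network`.
#' @export
ego_network <- function(root, followers, followees, edges,
                        k_in = length(followers), k_out = length(followees)) {
  followers <- unique(as.character(followers))
  followees <- unique(as.character(followees))
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2L || nrow(edges) == 0L)
  if (nrow(edges)) {
    storage.mode(edges) <- "character"
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  }
  key <- if (nrow(edges)) unique(paste(edges[, 1L], edges[, 2L], sep = "\r"))
         else character(0)
  net <- structure(list(root = as.character(root), followers = followers,
                        followees = followees, edge_keys = key,
                        m1 = length(followers), m2 = length(followees),
                        k_in = as.integer(k_in), k_out = as.integer(k_out)),
                   class = "ego_network")
  if (!all(has_edge(net, followers, root)))
    stop("every sampled follower must have an edge to the root")
  if (!all(has_edge(net, root, followees)))
    stop("the root must have an edge to every sampled followee")
  if (net$m1 > net$k_in || net$m2 > net$k_out)
    stop("sampled neighbor counts cannot exceed total degree counts")
  net
}

has_edge <- function(net, from, to) {
  # paste() would recycle a zero-length side up to the other one's length
  if (!length(from) || !length(to)) return(logical(0))
  paste(from, to, sep = "\r") %in% net$edge_keys
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network root:", x$root, "| m1:", x$m1, "of", x$k_in,
      "followers | m2:", x$m2, "of", x$k_out, "followees |",
      length(x$edge_keys), "edges>\n")
  invisible(x)
}

#' Sample up to `cap` followers and followees uniformly at random
#'
#' All neighbors are retained when there are no more than `cap` of them;
#' otherwise exactly `cap` are drawn without replacement. Reproducible under
#' `seed`.
#'
#' @param full_followers,full_followees Character vectors of all neighbor
#'   ids.
#' @param cap Sampling cap per side (default 100).
#' @param seed Optional integer seed.
#' @return List with `followers` and `followees`.
#' @export
sample_neighbors <- function(full_followers, full_followees, cap = 100L,
                             seed = NULL) {
  stopifnot(cap >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pick <- function(x) {
    if (length(x) <= cap) x else sample(x, cap)
  }
  list(followers = pick(full_followers), followees = pick(full_followees))
}

#' Reciprocal neighbors derived from the sampled followers
#'
#' The sampled followers whom the root follows back.
#'
#' @param net An [ego_network()].
#' @return Character vector of user ids.
#' @export
reciprocal_neighbors_from_followers <- function(net) {
  net$followers[has_edge(net, net$root, net$followers)]
}

#' Reciprocal neighbors derived from the sampled followees
#'
#' The sampled followees who follow the root back.
#'
#' @param net An [ego_network()].
#' @return Character vector of user ids.
#' @export
reciprocal_neighbors_from_followees <- function(net) {
  net$followees[has_edge(net, net$followees, net$root)]
}

#' Reciprocity over sampled followers (r1) or followees (r2)
#'
#' `r1` is the number of follower-derived reciprocal neighbors divided by
#' the number of sampled followers `m1`; `r2` is its followee-side
#' counterpart over `m2`. Either is undefined (`NA`) when the respective
#' side has fewer than `min_neighbors` sampled neighbors, since the ratio is
#' unreliable at small counts.
#'
#' @param net An [ego_network()].
#' @param min_neighbors Guard on the sampled count (default 5).
#' @return Numeric in `[0, 1]`, or `NA` when undefined.
#' @export
reciprocity_r1 <- function(net, min_neighbors = 5L) {
  if (net$m1 < min_neighbors) return(NA_real_)
  length(reciprocal_neighbors_from_followers(net)) / net$m1
}

#' @rdname reciprocity_r1
#' @export
reciprocity_r2 <- function(net, min_neighbors = 5L) {
  if (net$m2 < min_neighbors) return(NA_real_)
  length(reciprocal_neighbors_from_followees(net)) / net$m2
}

#' Restricted local clustering coefficients
#'
#' Clustering is measured over unordered pairs of the root's reciprocal
#' neighbors, derived either from the sampled followers (`C1`, `C1'`) or
#' the sampled followees (`C2`, `C2'`). The strict variant counts a pair
#' when the two neighbors are reciprocal neighbors of each other (both
#' directed edges present); the weak variant counts a pair joined by at
#' least one edge in either direction, so strict <= weak always. Undefined
#' (`NA`) when the source side has fewer than `min_neighbors` sampled
#' neighbors, or when fewer than 2 reciprocal neighbors exist (no pairs).
#'
#' @param net An [ego_network()].
#' @param source `"followers"` (C1 family) or `"followees"` (C2 family).
#' @param strength `"strict"` (both edges) or `"weak"` (at least one).
#' @param min_neighbors Guard on the sampled count of the source side.
#' @return Numeric in `[0, 1]`, or `NA` when undefined.
#' @export
clustering_coefficient <- function(net,
                                   source = c("followers", "followees"),
                                   strength = c("strict", "weak"),
                                   min_neighbors = 5L) {
  source <- match.arg(source)
  strength <- match.arg(strength)
  m_side <- if (source == "followers") net$m1 else net$m2
  if (m_side < min_neighbors) return(NA_real_)
  rn <- if (source == "followers") reciprocal_neighbors_from_followers(net)
        else reciprocal_neighbors_from_followees(net)
  k <- length(rn)
  if (k < 2L) return(NA_real_)
  pairs <- utils::combn(rn, 2L)
  fwd <- has_edge(net, pairs[1L, ], pairs[2L, ])
  bwd <- has_edge(net, pairs[2L, ], pairs[1L, ])
  hit <- if (strength == "strict") fwd & bwd else fwd | bwd
  sum(hit) / ncol(pairs)
}

#' Average neighbor alignment index (homophily statistic)
#'
#' Arithmetic mean of the alignment index over the root's sampled followers
#' or followees for which an index is available in `alpha_map` (those users
#' had enough eligible texts). Undefined (`NA`) when no neighbor on the
#' requested side has a computable index. The root's own index is never
#' included.
#'
#' @param net An [ego_network()].
#' @param alpha_map Named numeric vector mapping user id to alignment index.
#' @param side `"follower"` or `"followee"`.
#' @return Mean alignment index, or `NA` when undefined.
#' @export
homophily_avg <- function(net, alpha_map,
                          side = c("follower", "followee")) {
  side <- match.arg(side)
  ids <- if (side == "follower") net$followers else net$followees
  a <- alpha_map[ids[ids %in% names(alpha_map)]]
  if (!length(a)) return(NA_real_)
  mean(a)
}

#' Mean alignment index of reciprocal vs nonreciprocal followers
#'
#' Splits the sampled followers into those the root follows back
#' (reciprocal neighbors) and the rest, and averages the alignment index
#' within each subset over the users with a computable index. Either average
#' is `NA` when its subset is empty or has no computable index.
#'
#' @param net An [ego_network()].
#' @param alpha_map Named numeric vector mapping user id to alignment index.
#' @return Named numeric vector `reciprocal`, `nonreciprocal`.
#' @export
reciprocal_split_avg <- function(net, alpha_map) {
  rec <- reciprocal_neighbors_from_followers(net)
  nonrec <- setdiff(net$followers, rec)
  avg <- function(ids) {
    a <- alpha_map[ids[ids %in% names(alpha_map)]]
    if (!length(a)) NA_real_ else mean(a)
  }
  c(reciprocal = avg(rec), nonreciprocal = avg(nonrec))
}

#' All network indexes for one root user
#'
#' @param net An [ego_network()].
#' @param alpha_map Optional named numeric vector of alignment indexes; when
#'   omitted the homophily columns are `NA`.
#' @param min_neighbors Guard for the reciprocity and clustering indexes.
#' @return One-row data.frame with `root`, `m1`, `m2`, `k_in`, `k_out`,
#'   `r1`, `r2`, `C1`, `C1p`, `C2`, `C2p`, `avg_alpha_follower`,
#'   `avg_alpha_followee`, `avg_alpha_reciprocal`, `avg_alpha_nonreciprocal`.
#' @export
ego_indexes <- function(net, alpha_map = NULL, min_neighbors = 5L) {
  hom <- if (is.null(alpha_map)) {
    c(f1 = NA_real_, f2 = NA_real_, rec = NA_real_, non = NA_real_)
  } else {
    sp <- reciprocal_split_avg(net, alpha_map)
    c(f1 = homophily_avg(net, alpha_map, "follower"),
      f2 = homophily_avg(net, alpha_map, "followee"),
      rec = sp[["reciprocal"]], non = sp[["nonreciprocal"]])
  }
  data.frame(
    root = net$root, m1 = net$m1, m2 = net$m2,
    k_in = net$k_in, k_out = net$k_out,
    r1 = reciprocity_r1(net, min_neighbors),
    r2 = reciprocity_r2(net, min_neighbors),
    C1 = clustering_coefficient(net, "followers", "strict", min_neighbors),
    C1p = clustering_coefficient(net, "followers", "weak", min_neighbors),
    C2 = clustering_coefficient(net, "followees", "strict", min_neighbors),
    C2p = clustering_coefficient(net, "followees", "weak", min_neighbors),
    avg_alpha_follower = hom[["f1"]], avg_alpha_followee = hom[["f2"]],
    avg_alpha_reciprocal = hom[["rec"]],
    avg_alpha_nonreciprocal = hom[["non"]],
    stringsAsFactors = FALSE
  )
}

#' Survival probability of a degree distribution
#'
#' For a sample of non-negative integer degrees, returns the step function
#' `k -> fraction of values >= k`: nonincreasing, right-continuous, equal to
#' 1 at `k = 0`.
#'
#' @param values Non-negative integer vector (e.g. follower counts of the
#'   root users).
#' @return A vectorized function of `k`.
#' @export
#' @examples
#' surv <- survival_probability(c(1, 2, 3))
#' surv(c(0, 2, 4))  # 1, 2/3, 0
survival_probability <- function(values) {
  stopifnot(length(values) > 0L, all(values >= 0))
  values <- sort(values)
  n <- length(values)
  function(k) {
    vapply(k, function(kk) (n - findInterval(kk - 1e-9, values)) / n,
           numeric(1))
  }
}

#' Compute indexes for many roots from edge-list input
#'
#' Convenience wrapper over the file-level interface: takes an edge list,
#' a roots table and an alignment map, builds each root's sampled network
#' (sampling neighbors down to `cap` when needed) and stacks the per-root
#' indexes.
#'
#' @param edges Two-column data.frame (`source_id`, `target_id`).
#' @param roots data.frame with `root_id`, `k_in`, `k_out` and optionally
#'   `group`.
#' @param alpha_map Optional named numeric vector of alignment indexes.
#' @param cap Neighbor sampling cap per side (default 100).
#' @param seed Optional seed for the neighbor sampling.
#' @param min_neighbors Index guard (default 5).
#' @return data.frame, one row per root, as in [ego_indexes()] (plus
#'   `group` when present in `roots`).
#' @export
ego_indexes_table <- function(edges, roots, alpha_map = NULL, cap = 100L,
                              seed = NULL, min_neighbors = 5L) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(roots)), function(i) {
    rid <- roots$root_id[i]
    full_followers <- edges$source_id[edges$target_id == rid]
    full_followees <- edges$target_id[edges$source_id == rid]
    samp <- sample_neighbors(full_followers, full_followees, cap)
    nodes <- unique(c(rid, samp$followers, samp$followees))
    sub <- edges[edges$source_id %in% nodes & edges$target_id %in% nodes, ]
    net <- ego_network(rid, samp$followers, samp$followees, sub,
                       k_in = roots$k_in[i], k_out = roots$k_out[i])
    ego_indexes(net, alpha_map, min_neighbors)
  })
  res <- do.call(rbind, out)
  if ("group" %in% names(roots)) res$group <- roots$group
  res
}
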
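# Independent brute-force oracles. These re-derive every index from first
# principles (explicit loops over the raw edge matrix / score vectors) and
# must never call into the package code paths they check.

# edge present in a raw two-column character matrix?
orc_has_edge <- function(edges, from, to) {
  if (!nrow(edges)) return(FALSE)
  any(edges[, 1L] == from & edges[, 2L] == to)
}

orc_reciprocal_from_followers <- function(root, followers, edges) {
  followers[vapply(followers, function(f) orc_has_edge(edges, root, f),
                   logical(1))]
}

orc_reciprocal_from_followees <- function(root, followees, edges) {
  followees[vapply(followees, function(g) orc_has_edge(edges, g, root),
                   logical(1))]
}

orc_r <- function(root, side_ids, edges, from_followers, min_n = 5L) {
  m <- length(side_ids)
  if (m < min_n) return(NA_real_)
  rn <- if (from_followers) orc_reciprocal_from_followers(root, side_ids, edges)
        else orc_reciprocal_from_followees(root, side_ids, edges)
  length(rn) / m
}

orc_clustering <- function(root, side_ids, edges, from_followers, strict,
                           min_n = 5L) {
  if (length(side_ids) < min_n) return(NA_real_)
  rn <- if (from_followers) orc_reciprocal_from_followers(root, side_ids, edges)
        else orc_reciprocal_from_followees(root, side_ids, edges)
  k <- length(rn)
  if (k < 2L) return(NA_real_)
  hits <- 0L; total <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      total <- total + 1L
      ab <- orc_has_edge(edges, rn[i], rn[j])
      ba <- orc_has_edge(edges, rn[j], rn[i])
      if ((strict && ab && ba) || (!strict && (ab || ba)))
        hits <- hits + 1L
    }
  }
  hits / total
}

orc_homophily <- function(side_ids, alpha_map) {
  vals <- c()
  for (id in side_ids) {
    if (id %in% names(alpha_map)) vals <- c(vals, alpha_map[[id]])
  }
  if (!length(vals)) NA_real_ else sum(vals) / length(vals)
}

# pairwise-concordance AUC with half credit for ties
orc_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# nearest-rank "top 10% value": the ceiling(0.1 n)-th largest score
orc_alignment <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  s[ceiling(0.1 * length(s))]
}

# exact two-sided rank-sum p by full enumeration over rank assignments
# (distinct pooled values only)
orc_ranksum_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  rs <- sort(r)
  Us <- apply(sets, 2L, function(ix) sum(rs[ix])) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  list(statistic = U_obs, p_value = min(1, p))
}

# a random sampled ego network of at most 15 nodes, returned both as an
# ego_network object and as the raw pieces the oracles consume
random_ego_net <- function(p_edge = 0.3) {
  n_f <- sample(0:7, 1L)
  n_g <- sample(0:7, 1L)
  fol <- if (n_f) paste0("f", seq_len(n_f)) else character(0)
  fee <- if (n_g) paste0("g", seq_len(n_g)) else character(0)
  if (n_f && stats::runif(1) < 0.5) {
    fee <- unique(c(fee, sample(fol, sample.int(n_f, 1L))))
  }
  edges <- rbind(
    if (length(fol)) cbind(fol, "u"),
    if (length(fee)) cbind("u", fee)
  )
  nodes <- unique(c(fol, fee))
  # random follow-backs from the root and edges among neighbors
  for (f in fol) {
    if (!(f %in% fee) && stats::runif(1) < 0.5) edges <- rbind(edges, c("u", f))
  }
  for (g in fee) {
    if (stats::runif(1) < 0.5) edges <- rbind(edges, c(g, "u"))
  }
  if (length(nodes) >= 2L) {
    pr <- utils::combn(nodes, 2L)
    for (j in seq_len(ncol(pr))) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, pr[, j])
      if (stats::runif(1) < p_edge) edges <- rbind(edges, rev(pr[, j]))
    }
  }
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  edges <- unique(edges)
  alpha_ids <- nodes[stats::runif(length(nodes)) < 0.6]
  alpha_map <- stats::setNames(round(stats::runif(length(alpha_ids)), 3),
                               alpha_ids)
  list(net = ego_network("u", fol, fee, edges),
       root = "u", followers = fol, followees = fee, edges = edges,
       alpha_map = alpha_map)
}

# the hypothetical example networks used in the package documentation:
# (a) reciprocity: 5 followers, 6 followees, 2 reciprocal neighbors
fig_reciprocity_net <- function() {
  fol <- paste0("f", 1:5)
  fee <- c("f1", "f2", paste0("g", 1:4))
  edges <- rbind(cbind(fol, "u"), cbind("u", fee))
  ego_network("u", fol, fee, edges)
}

# (b) homophily: 3 followers (alpha .5/.6/.7; .6 and .7 reciprocated),
#     4 followees (alpha .3/.6/.7/.4)
fig_homophily_net <- function() {
  fol <- c("a", "b", "c")             # alpha 0.5, 0.6, 0.7
  fee <- c("p", "q", "r", "s")        # alpha 0.3, 0.6, 0.7, 0.4
  edges <- rbind(cbind(fol, "u"), cbind("u", fee),
                 c("u", "b"), c("u", "c"))
  list(net = ego_network("u", fol, fee, edges),
       alpha_map = c(a = 0.5, b = 0.6, c = 0.7,
                     p = 0.3, q = 0.6, r = 0.7, s = 0.4))
}

make_docs <- function(token_lists) {
  lapply(seq_along(token_lists), function(i)
    acenet:::new_cleaned_document(as.character(i), token_lists[[i]]))
}
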
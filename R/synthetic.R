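#' Specification for a synthetic two-class corpus
#'
#' The generator emulates the two training corpora: two classes of short
#' texts (6-45 words, matching the eligibility floor and the classifier's
#' input cap) drawn token-wise from class-specific signal vocabularies with
#' a controlled mixing fraction. With mixing `epsilon < 0.5` the classes are
#' separable and a competent classifier approaches perfect held-out
#' accuracy.
#'
#' @param n_pos,n_neg Documents per class.
#' @param vocab_size Total vocabulary size; split evenly into the two signal
#'   subsets (default 400).
#' @param epsilon Fraction of tokens drawn from the other class's subset
#'   (default 0.1; must be < 0.5).
#' @param length_range Inclusive word-count range, default `c(6, 45)`.
#' @param seed Integer seed.
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_pos = 1000L, n_neg = 1000L, vocab_size = 400L,
                        epsilon = 0.1, length_range = c(6L, 45L),
                        seed = 1L) {
  stopifnot(epsilon >= 0, epsilon < 0.5,
            length_range[1] > 5L, length_range[2] <= 45L,
            length_range[1] <= length_range[2], vocab_size >= 4L)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 vocab_size = as.integer(vocab_size), epsilon = epsilon,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a labeled synthetic corpus
#'
#' @param spec A [corpus_spec()].
#' @return A [labeled_corpus()]; reproducible bit-for-bit under the spec's
#'   seed.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  half <- spec$vocab_size %/% 2L
  vocab_pos <- sprintf("pos%04d", seq_len(half))
  vocab_neg <- sprintf("neg%04d", seq_len(spec$vocab_size - half))
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    own <- if (labels[i] == 1L) vocab_pos else vocab_neg
    other <- if (labels[i] == 1L) vocab_neg else vocab_pos
    cross <- stats::runif(lens[i]) < spec$epsilon
    toks <- character(lens[i])
    toks[!cross] <- sample(own, sum(!cross), replace = TRUE)
    toks[cross] <- sample(other, sum(cross), replace = TRUE)
    docs[[i]] <- new_cleaned_document(sprintf("doc%05d", i), toks)
  }
  ord <- sample.int(n)
  labeled_corpus(docs[ord], labels[ord])
}

#' Specification for synthetic per-user score streams
#'
#' Emulates the populations behind the alignment-index analysis: each user
#' gets at least 30 eligible mention scores. ACE users receive a planted
#' fraction (at least 10%, placed deterministically) of high scores at or
#' above 0.5, which forces the top-10% alignment index to at least 0.5;
#' users of the two non-ACE groups receive only scores strictly below 0.3,
#' with the first non-ACE group's scores centred higher than the second's,
#' mirroring the observed ordering between users sampled by parent-related
#' and parenting-unrelated keywords.
#'
#' @param n_users Named integer vector of users per group; names `ACE`,
#'   `NON_ACE_1`, `NON_ACE_2`.
#' @param n_texts Eligible texts per user (default 40; must be >= 30).
#' @param high_fraction Fraction of an ACE user's scores planted high
#'   (default 0.15; must be >= 0.1).
#' @param seed Integer seed.
#' @return List of class `user_stream_spec`.
#' @export
user_stream_spec <- function(n_users = c(ACE = 100L, NON_ACE_1 = 100L,
                                         NON_ACE_2 = 100L),
                             n_texts = 40L, high_fraction = 0.15,
                             seed = 1L) {
  stopifnot(all(c("ACE", "NON_ACE_1", "NON_ACE_2") %in% names(n_users)),
            n_texts >= 30L, high_fraction >= 0.1, high_fraction <= 1)
  structure(list(n_users = n_users, n_texts = as.integer(n_texts),
                 high_fraction = high_fraction, seed = as.integer(seed)),
            class = "user_stream_spec")
}

#' Generate per-user score streams with planted categories
#'
#' @param spec A [user_stream_spec()].
#' @return data.frame with columns `user_id`, `group`, `word_count` (all
#'   eligible, set to 6) and `ace_mention_score`; suitable for
#'   [profile_users()].
#' @export
generate_user_streams <- function(spec = user_stream_spec()) {
  stopifnot(inherits(spec, "user_stream_spec"))
  set.seed(spec$seed)
  nt <- spec$n_texts
  n_high <- ceiling(spec$high_fraction * nt)
  rows <- list()
  uid <- 0L
  for (g in c("ACE", "NON_ACE_1", "NON_ACE_2")) {
    for (j in seq_len(spec$n_users[[g]])) {
      uid <- uid + 1L
      s <- switch(g,
        ACE = {
          # planted high block guarantees the top-10% value >= 0.5
          c(stats::runif(n_high, 0.55, 0.95),
            stats::runif(nt - n_high, 0.00, 0.45))
        },
        NON_ACE_1 = 0.29 * stats::rbeta(nt, 4, 2),
        NON_ACE_2 = 0.29 * stats::rbeta(nt, 2, 4))
      rows[[uid]] <- data.frame(
        user_id = sprintf("u%05d", uid), group = g,
        word_count = 6L, ace_mention_score = s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Specification for synthetic egocentric networks
#'
#' Emulates the sampled directed follow networks around root users. Total
#' degrees are heavy-tailed (discrete log-normal, truncated to the observed
#' ceiling of 7089); each follower is followed back independently with
#' probability `p_back`; each pair of same-side reciprocal neighbors is
#' closed into a triangle edge with probability `p_tri` (reciprocal with
#' probability 1/2, one-way otherwise, so the expected strict clustering is
#' `p_tri / 2` and the weak one `p_tri`); each neighbor shares the root's
#' group with probability `h` and otherwise draws uniformly from the other
#' groups (`h = NULL` means group-blind: uniform over all three); a neighbor
#' has a computable alignment index with probability `p_alpha`, drawn from
#' its group's index distribution (normal, truncated to `[0, 1]`, with the
#' group means/SDs observed for sampled users: 0.81/0.12, 0.44/0.09,
#' 0.36/0.13).
#'
#' @param p_back Follow-back probability (default 0.4).
#' @param p_tri Triangle-closure probability per reciprocal pair
#'   (default 0.1).
#' @param h Homophily mixing in `[0, 1]`, or `NULL` for group-blind
#'   neighbor groups (default 0.6).
#' @param p_alpha Probability a neighbor has a computable alignment index
#'   (default 0.5).
#' @param degree_meanlog,degree_sdlog Log-normal parameters of the total
#'   degrees (defaults 5.3 and 1.4).
#' @param degree_cap Truncation ceiling (default 7089).
#' @param cap Neighbor sampling cap per side (default 100).
#' @param fixed_degrees Optional length-2 integer vector `c(k_in, k_out)`
#'   overriding the degree draw, for controlled experiments.
#' @return List of class `ego_net_spec`.
#' @export
ego_net_spec <- function(p_back = 0.4, p_tri = 0.1, h = 0.6, p_alpha = 0.5,
                         degree_meanlog = 5.3, degree_sdlog = 1.4,
                         degree_cap = 7089L, cap = 100L,
                         fixed_degrees = NULL) {
  stopifnot(p_back >= 0, p_back <= 1, p_tri >= 0, p_tri <= 1,
            is.null(h) || (h >= 0 && h <= 1), p_alpha >= 0, p_alpha <= 1)
  structure(list(p_back = p_back, p_tri = p_tri, h = h, p_alpha = p_alpha,
                 degree_meanlog = degree_meanlog,
                 degree_sdlog = degree_sdlog,
                 degree_cap = as.integer(degree_cap), cap = as.integer(cap),
                 fixed_degrees = fixed_degrees),
            class = "ego_net_spec")
}

ace_groups <- c("ACE", "NON_ACE_1", "NON_ACE_2")

# group-specific alignment-index distributions (truncated normal on [0, 1])
draw_alpha <- function(group, n) {
  mu <- c(ACE = 0.81, NON_ACE_1 = 0.44, NON_ACE_2 = 0.36)[[group]]
  sdv <- c(ACE = 0.12, NON_ACE_1 = 0.09, NON_ACE_2 = 0.13)[[group]]
  pmin(1, pmax(0, stats::rnorm(n, mu, sdv)))
}

draw_degree <- function(spec, n) {
  k <- round(stats::rlnorm(n, spec$degree_meanlog, spec$degree_sdlog))
  pmin(pmax(k, 0L), spec$degree_cap)
}

#' Generate one synthetic egocentric network
#'
#' @param spec An [ego_net_spec()].
#' @param root_group One of `"ACE"`, `"NON_ACE_1"`, `"NON_ACE_2"`.
#' @param root_id Identifier for the root (default `"root"`).
#' @param seed Optional integer seed.
#' @return List with `net` (an [ego_network()]), `alpha_map` (named numeric
#'   vector over neighbors with a computable index) and `neighbor_groups`.
#' @export
generate_ego_network <- function(spec = ego_net_spec(), root_group = "ACE",
                                 root_id = "root", seed = NULL) {
  stopifnot(inherits(spec, "ego_net_spec"), root_group %in% ace_groups)
  if (!is.null(seed)) set.seed(seed)
  deg <- if (is.null(spec$fixed_degrees)) draw_degree(spec, 2L)
         else spec$fixed_degrees
  k_in <- deg[1]; k_out <- deg[2]
  m1 <- min(k_in, spec$cap)
  m2_free <- min(k_out, spec$cap)
  followers <- if (m1 > 0) paste0(root_id, "_f", seq_len(m1)) else character(0)
  edges <- cbind(followers, rep(root_id, m1))
  # follow-back draws; reciprocated followers are also followees of the root
  back <- followers[stats::runif(m1) < spec$p_back]
  followees <- if (m2_free > 0) paste0(root_id, "_g", seq_len(m2_free))
               else character(0)
  if (length(followees))
    edges <- rbind(edges, cbind(rep(root_id, length(followees)), followees))
  if (length(back))
    edges <- rbind(edges, cbind(rep(root_id, length(back)), back))
  # the sampled followee set stays disjoint from the followers, keeping
  # m2 = min(k_out, cap); reciprocated followers are followees of the root
  # but are not part of the followee sample
  followees_all <- followees
  # followees (other than reciprocated followers) follow back with p_back
  back2 <- followees[stats::runif(length(followees)) < spec$p_back]
  if (length(back2))
    edges <- rbind(edges, cbind(back2, rep(root_id, length(back2))))
  # triangle closure among same-side reciprocal neighbor pairs
  close_pairs <- function(rn) {
    if (length(rn) < 2L) return(NULL)
    pr <- utils::combn(rn, 2L)
    closed <- stats::runif(ncol(pr)) < spec$p_tri
    if (!any(closed)) return(NULL)
    pr <- pr[, closed, drop = FALSE]
    out <- NULL
    for (j in seq_len(ncol(pr))) {
      if (stats::runif(1) < 0.5) {                       # reciprocal pair
        out <- rbind(out, c(pr[1, j], pr[2, j]), c(pr[2, j], pr[1, j]))
      } else if (stats::runif(1) < 0.5) {                # one-way edge
        out <- rbind(out, c(pr[1, j], pr[2, j]))
      } else {
        out <- rbind(out, c(pr[2, j], pr[1, j]))
      }
    }
    out
  }
  edges <- rbind(edges, close_pairs(back), close_pairs(back2))
  neighbors <- unique(c(followers, followees_all))
  grp <- vapply(neighbors, function(id) {
    if (is.null(spec$h)) sample(ace_groups, 1L)
    else if (stats::runif(1) < spec$h) root_group
    else sample(setdiff(ace_groups, root_group), 1L)
  }, character(1))
  has_a <- stats::runif(length(neighbors)) < spec$p_alpha
  alpha_map <- stats::setNames(
    unlist(lapply(which(has_a), function(i) draw_alpha(grp[[i]], 1L)),
           use.names = FALSE),
    neighbors[has_a])
  if (!length(alpha_map)) alpha_map <- stats::setNames(numeric(0),
                                                       character(0))
  net <- ego_network(root_id, followers, followees_all, edges,
                     k_in = max(k_in, length(followers)),
                     k_out = max(k_out, length(followees_all)))
  list(net = net, alpha_map = alpha_map,
       neighbor_groups = grp)
}

#' Generate a whole egocentric-network study
#'
#' Draws `n_roots` roots per group (group-specific specs allowed), computes
#' every network index per root, and returns the stacked table ready for
#' [compare_groups()].
#'
#' @param n_roots Named integer vector of roots per group.
#' @param specs Either a single [ego_net_spec()] used for all groups or a
#'   named list of per-group specs.
#' @param seed Integer seed.
#' @return data.frame of per-root indexes with a `group` column.
#' @export
generate_ego_study <- function(n_roots = c(ACE = 100L, NON_ACE_1 = 100L,
                                           NON_ACE_2 = 100L),
                               specs = ego_net_spec(), seed = 1L) {
  if (inherits(specs, "ego_net_spec"))
    specs <- stats::setNames(rep(list(specs), 3L), ace_groups)
  stopifnot(all(names(n_roots) %in% ace_groups))
  set.seed(seed)
  rows <- list(); i <- 0L
  for (g in names(n_roots)) {
    for (j in seq_len(n_roots[[g]])) {
      i <- i + 1L
      gen <- generate_ego_network(specs[[g]], g,
                                  root_id = sprintf("%s_r%04d", g, j))
      row <- ego_indexes(gen$net, gen$alpha_map)
      row$group <- g
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows)
}
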
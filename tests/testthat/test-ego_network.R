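test_that("ego_network validates its invariants", {
  expect_error(ego_network("u", "f1", character(0),
                           rbind(c("u", "f1"))),
               "follower must have an edge")
  expect_error(ego_network("u", character(0), "g1",
                           rbind(c("g1", "u"))),
               "edge to every sampled followee")
  expect_error(ego_network("u", "f1", character(0),
                           rbind(c("f1", "u"), c("u", "u"))), "self-loops")
  expect_error(ego_network("u", paste0("f", 1:3), character(0),
                           rbind(cbind(paste0("f", 1:3), "u")), k_in = 2),
               "exceed total degree")
})

test_that("sample_neighbors caps and reproduces", {
  s <- sample_neighbors(paste0("f", 1:50), paste0("g", 1:3), cap = 100)
  expect_length(s$followers, 50L)
  expect_length(s$followees, 3L)

  s1 <- sample_neighbors(paste0("f", 1:500), character(0), cap = 100,
                         seed = 4)
  expect_length(unique(s1$followers), 100L)
  s2 <- sample_neighbors(paste0("f", 1:500), character(0), cap = 100,
                         seed = 4)
  expect_identical(s1, s2)
})

test_that("reciprocity matches the depicted worked example and guards", {
  net <- fig_reciprocity_net()
  expect_setequal(reciprocal_neighbors_from_followers(net), c("f1", "f2"))
  expect_equal(reciprocity_r1(net), 2 / 5)
  expect_equal(reciprocity_r2(net), 1 / 3)

  # guards: fewer than 5 sampled neighbors on the relevant side
  small <- ego_network("u", paste0("f", 1:4), paste0("g", 1:5),
                       rbind(cbind(paste0("f", 1:4), "u"),
                             cbind("u", paste0("g", 1:5))))
  expect_true(is.na(reciprocity_r1(small)))
  expect_equal(reciprocity_r2(small), 0)
  small2 <- ego_network("u", paste0("f", 1:5), paste0("g", 1:3),
                        rbind(cbind(paste0("f", 1:5), "u"),
                              cbind("u", paste0("g", 1:3))))
  expect_true(is.na(reciprocity_r2(small2)))

  # all followers reciprocated
  full <- ego_network("u", paste0("f", 1:10), paste0("f", 1:10),
                      rbind(cbind(paste0("f", 1:10), "u"),
                            cbind("u", paste0("f", 1:10))))
  expect_equal(reciprocity_r1(full), 1.0)
  expect_setequal(reciprocal_neighbors_from_followers(full),
                  paste0("f", 1:10))
})

test_that("clustering counts strict vs weak pairs as defined", {
  base <- function(extra) {
    fol <- paste0("f", 1:5)
    ego_network("u", fol, fol,
                rbind(cbind(fol, "u"), cbind("u", fol), extra))
  }
  # all three reciprocal neighbors mutually reciprocal -> both variants 1
  tri <- base(rbind(c("f1", "f2"), c("f2", "f1"), c("f1", "f3"),
                    c("f3", "f1"), c("f2", "f3"), c("f3", "f2"),
                    c("f1", "f4"), c("f4", "f1"), c("f1", "f5"),
                    c("f5", "f1"), c("f2", "f4"), c("f4", "f2"),
                    c("f2", "f5"), c("f5", "f2"), c("f3", "f4"),
                    c("f4", "f3"), c("f3", "f5"), c("f5", "f3"),
                    c("f4", "f5"), c("f5", "f4")))
  expect_equal(clustering_coefficient(tri, "followers", "strict"), 1)
  expect_equal(clustering_coefficient(tri, "followers", "weak"), 1)

  # a single one-way edge between two reciprocal neighbors counts for the
  # weak variant only
  fol <- paste0("f", 1:5)
  net1 <- ego_network("u", fol, c("f1", "f2"),
                      rbind(cbind(fol, "u"), c("u", "f1"), c("u", "f2"),
                            c("f1", "f2")))
  expect_equal(clustering_coefficient(net1, "followers", "strict"), 0)
  expect_equal(clustering_coefficient(net1, "followers", "weak"), 1)

  # guards: < 5 sampled on the source side, or < 2 reciprocal neighbors
  small <- ego_network("u", paste0("f", 1:4), character(0),
                       cbind(paste0("f", 1:4), "u"))
  expect_true(is.na(clustering_coefficient(small, "followers", "strict")))
  lone <- ego_network("u", fol, "f1",
                      rbind(cbind(fol, "u"), c("u", "f1")))
  expect_true(is.na(clustering_coefficient(lone, "followers", "strict")))
})

test_that("homophily averages match the depicted worked example", {
  fh <- fig_homophily_net()
  expect_equal(homophily_avg(fh$net, fh$alpha_map, "follower"), 0.6)
  expect_equal(homophily_avg(fh$net, fh$alpha_map, "followee"), 0.5)
  sp <- reciprocal_split_avg(fh$net, fh$alpha_map)
  expect_equal(sp[["reciprocal"]], 0.65)
  expect_equal(sp[["nonreciprocal"]], 0.5)

  # no computable neighbor index -> undefined
  expect_true(is.na(homophily_avg(fh$net, c(zz = 0.4), "follower")))
  # all followers reciprocated -> nonreciprocal average undefined
  full <- ego_network("u", c("a", "b"), c("a", "b"),
                      rbind(cbind(c("a", "b"), "u"),
                            cbind("u", c("a", "b"))))
  expect_true(is.na(reciprocal_split_avg(full,
                                         c(a = 0.2, b = 0.4))[["nonreciprocal"]]))
})

test_that("indexes agree with exhaustive enumeration on random networks", {
  set.seed(47)
  for (i in 1:300) {
    rn <- random_ego_net()
    idx <- ego_indexes(rn$net, rn$alpha_map)
    expect_equal(idx$r1, orc_r(rn$root, rn$followers, rn$edges, TRUE))
    expect_equal(idx$r2, orc_r(rn$root, rn$followees, rn$edges, FALSE))
    expect_equal(idx$C1,
                 orc_clustering(rn$root, rn$followers, rn$edges, TRUE, TRUE))
    expect_equal(idx$C1p,
                 orc_clustering(rn$root, rn$followers, rn$edges, TRUE, FALSE))
    expect_equal(idx$C2,
                 orc_clustering(rn$root, rn$followees, rn$edges, FALSE, TRUE))
    expect_equal(idx$C2p,
                 orc_clustering(rn$root, rn$followees, rn$edges, FALSE, FALSE))
    expect_equal(idx$avg_alpha_follower,
                 orc_homophily(rn$followers, rn$alpha_map))
    expect_equal(idx$avg_alpha_followee,
                 orc_homophily(rn$followees, rn$alpha_map))
    # strict <= weak whenever both are defined
    if (!is.na(idx$C1)) expect_lte(idx$C1, idx$C1p)
    if (!is.na(idx$C2)) expect_lte(idx$C2, idx$C2p)
  }
})

test_that("follower- and followee-derived reciprocal sets agree on fully
           sampled networks", {
  set.seed(53)
  for (i in 1:50) {
    # a global digraph on 12 nodes; the ego network takes ALL in- and
    # out-neighbors of the root, so neither sampling cap binds
    nodes <- paste0("v", 1:12)
    pairs <- expand.grid(a = c("u", nodes), b = c("u", nodes),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    edges <- as.matrix(pairs[stats::runif(nrow(pairs)) < 0.25, ])
    fol <- edges[edges[, 2] == "u", 1]
    fee <- edges[edges[, 1] == "u", 2]
    if (!length(fol) || !length(fee)) next
    net <- ego_network("u", fol, fee, edges)
    expect_setequal(reciprocal_neighbors_from_followers(net),
                    reciprocal_neighbors_from_followees(net))
  }
})

test_that("survival_probability is a proper nonincreasing step function", {
  surv <- survival_probability(c(1, 2, 3))
  expect_equal(surv(2), 2 / 3)
  expect_equal(surv(0), 1.0)
  expect_equal(surv(10), 0.0)

  set.seed(59)
  vals <- sample(0:50, 40, replace = TRUE)
  sv <- survival_probability(vals)
  ks <- seq(0, 55, by = 0.5)
  out <- sv(ks)
  expect_true(all(diff(out) <= 0))
  expect_equal(out[1], 1.0)
  # constant between consecutive integers for integer-valued data
  expect_equal(sv(7), sv(6.5))
  # agrees with direct counting
  expect_equal(sv(13), mean(vals >= 13))
})

test_that("ego_indexes_table builds networks from edge-list input", {
  fol <- paste0("f", 1:5)
  fee <- c("f1", "f2", paste0("g", 1:4))
  edges <- data.frame(
    source_id = c(fol, rep("u", 6)),
    target_id = c(rep("u", 5), fee),
    stringsAsFactors = FALSE)
  roots <- data.frame(root_id = "u", k_in = 5L, k_out = 6L,
                      group = "ACE", stringsAsFactors = FALSE)
  tab <- ego_indexes_table(edges, roots,
                           alpha_map = c(f1 = 0.6, f2 = 0.7, f3 = 0.5))
  expect_equal(tab$r1, 0.4)
  expect_equal(tab$r2, 1 / 3)
  expect_equal(tab$avg_alpha_follower, 0.6)
  expect_equal(tab$group, "ACE")
})
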
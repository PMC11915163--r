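two_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- paste0("n", 1:8)
  g
}

test_that("module detection recovers planted cliques deterministically", {
  g <- two_cliques()
  p1 <- detect_modules(g, seed = 1)
  p2 <- detect_modules(g, seed = 1)
  expect_identical(p1$membership, p2$membership)
  mods <- p1$membership$module
  expect_identical(length(unique(mods)), 2L)
  expect_identical(length(unique(mods[1:4])), 1L)
  expect_identical(length(unique(mods[5:8])), 1L)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("m", 1:5)
  expect_identical(length(unique(detect_modules(k5)$membership$module)), 1L)
})

test_that("Zi and Pi follow their definitions on forced configurations", {
  g <- two_cliques()
  roles <- zi_pi(g, detect_modules(g))
  # bridge endpoints split edges 3:1 across modules -> pi = 1 - (9+1)/16
  expect_equal(roles$pi[roles$taxon_id == "n1"], 0.375, tolerance = 1e-12)
  # all-internal nodes have pi = 0
  expect_equal(roles$pi[roles$taxon_id == "n2"], 0)
  # equal within-module degree -> zi = 0 by the sd-zero convention
  expect_true(all(roles$zi == 0))
  # node with 2 edges split across 2 modules -> pi = 0.5
  star <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a"), to = c("b", "c")), directed = FALSE)
  part <- tibble::tibble(taxon_id = c("a", "b", "c"), module = c(1L, 1L, 2L))
  r2 <- zi_pi(star, part)
  expect_equal(r2$pi[r2$taxon_id == "a"], 0.5, tolerance = 1e-12)
})

test_that("keystone classification covers the (zi, pi) plane without gaps", {
  grid <- tidyr::expand_grid(zi = seq(-1, 4, by = 0.25),
                             pi = seq(0, 1, by = 0.05))
  out <- classify_keystones(grid)
  expected <- with(grid, ifelse(zi >= 2.5 & pi >= 0.62, "network_hub",
                         ifelse(zi >= 2.5, "module_hub",
                         ifelse(pi >= 0.62, "connector", "peripheral"))))
  expect_identical(out$role, expected)
  expect_identical(out$keystone, out$role != "peripheral")
  # printed boundary cases
  expect_identical(classify_keystones(tibble::tibble(zi = 2.6, pi = 0.5))$role,
                   "module_hub")
  expect_identical(classify_keystones(tibble::tibble(zi = 1.0, pi = 0.7))$role,
                   "connector")
  expect_identical(classify_keystones(tibble::tibble(zi = 2.5, pi = 0.62))$role,
                   "network_hub")
})

test_that("cohesion reproduces the hand-worked example and is linear in abundance", {
  ids <- c("t1", "t2", "t3")
  fit <- corr_fixture(list(list(1, 2, 0.5), list(1, 3, -0.4)), ids)
  rel <- abund_tbl(data.frame(taxon_id = ids, s1 = c(0.5, 0.3, 0.2)),
                   unit = "relative_fraction")
  ch <- community_cohesion(rel, fit, r_threshold = 0, p_threshold = 1)
  expect_equal(ch$samples$cohesion_pos, 0.40, tolerance = 1e-12)
  expect_equal(ch$samples$cohesion_neg, -0.28, tolerance = 1e-12)
  # zero correlations -> zero cohesion
  fit0 <- corr_fixture(list(), ids)
  ch0 <- community_cohesion(rel, fit0, r_threshold = 0, p_threshold = 1)
  expect_equal(ch0$samples$cohesion_pos, 0)
  expect_equal(ch0$samples$cohesion_neg, 0)
  # linearity: C(a p1 + (1-a) p2) = a C(p1) + (1-a) C(p2)
  p1 <- c(0.5, 0.3, 0.2); p2 <- c(0.1, 0.2, 0.7); a <- 0.3
  mix <- a * p1 + (1 - a) * p2
  ctab <- function(p) {
    community_cohesion(
      abund_tbl(data.frame(taxon_id = ids, s1 = p), unit = "relative_fraction"),
      fit, r_threshold = 0, p_threshold = 1)$samples
  }
  expect_equal(ctab(mix)$cohesion_pos,
               a * ctab(p1)$cohesion_pos + (1 - a) * ctab(p2)$cohesion_pos,
               tolerance = 1e-12)
  expect_equal(ctab(mix)$cohesion_neg,
               a * ctab(p1)$cohesion_neg + (1 - a) * ctab(p2)$cohesion_neg,
               tolerance = 1e-12)
  expect_error(community_cohesion(tiny_counts(), fit), "relative")
})

test_that("removal endpoints reproduce unperturbed and phylum-absent cohesion", {
  sim <- null_sim(n_taxa = 25, n_samples = 12, seed = 8, depth = 5000)
  fit <- sparcc(sim$prok, iterations = 10, seed = 2)
  rel <- to_relative(sim$prok)
  ph <- sim$taxonomy$phylum[1]
  tr <- removal_stability(rel, fit, sim$taxonomy, ph, fractions = c(0, 0.5, 1),
                          n_reps = 5, seed = 1, r_threshold = 0.2,
                          p_threshold = 1)
  full <- community_cohesion(rel, fit, r_threshold = 0.2, p_threshold = 1)
  expect_equal(tr$trajectory$cohesion_pos[1], mean(full$samples$cohesion_pos),
               tolerance = 1e-12)
  # fraction 1: identical to recomputing on the community without the phylum
  keep <- sim$taxonomy$taxon_id[sim$taxonomy$phylum != ph]
  sub <- to_relative(abund_tbl(sim$prok[sim$prok$taxon_id %in% keep, ],
                               unit = "reads"))
  absent <- community_cohesion(sub, fit, r_threshold = 0.2, p_threshold = 1)
  expect_equal(tr$trajectory$cohesion_pos[3], mean(absent$samples$cohesion_pos),
               tolerance = 1e-12)
  expect_error(removal_stability(rel, fit, sim$taxonomy, "NoSuchPhylum"),
               "no taxa")
})

test_that("focal association applies the edge-weight-sum rule", {
  edges <- data.frame(from = c("f1", "f1", "f2", "x3"),
                      to = c("x1", "x2", "x2", "x4"),
                      weight = c(0.7, 0.7, -0.65, 0.9))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  ab <- abund_tbl(data.frame(taxon_id = c("f1", "f2", "x1", "x2", "x3", "x4"),
                             s1 = c(10, 10, 30, 20, 20, 10)))
  fa <- focal_association(g, c("f1", "f2"), ab)
  cls <- stats::setNames(fa$nodes$class, fa$nodes$taxon_id)
  expect_identical(unname(cls["x1"]), "positive")       # single +0.7 edge
  expect_identical(unname(cls["x2"]), "positive")       # 0.7 - 0.65 = +0.05
  expect_identical(unname(cls["x3"]), "none")           # no focal edge
  expect_identical(unname(cls["x4"]), "none")
  fr <- fa$fractions
  expect_equal(fr$positive + fr$negative + fr$none + fr$focal, 1,
               tolerance = 1e-12)
  expect_equal(fr$positive, 50 / 100)
  expect_equal(fr$focal, 20 / 100)
  # all nodes unconnected to the focal set
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "x3", to = "x4", weight = 0.8), directed = FALSE)
  fa2 <- focal_association(g2, c("f1", "f2"), ab)
  expect_equal(fa2$fractions$none, 1 - fa2$fractions$focal, tolerance = 1e-12)
})
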
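test_that("basis-variance solve matches brute-force least squares at D = 4", {
  set.seed(1)
  m <- matrix(rpois(4 * 50, 40), nrow = 4,
              dimnames = list(paste0("z", 1:4), paste0("s", 1:50)))
  tbl <- abund_from_matrix(m)
  # exclusion disabled (threshold 1): the plain sparsity solve
  fit <- sparcc(tbl, exclusion_threshold = 1, seed = 1,
                fraction_method = "pseudocount")
  # independent oracle: least squares on the pairwise t_ij = w_i + w_j system
  fr <- (t(m) + 1) / rowSums(t(m) + 1)
  lf <- log(fr)
  pairs <- utils::combn(4, 2)
  tvals <- apply(pairs, 2, function(ij) stats::var(lf[, ij[1]] - lf[, ij[2]]))
  A <- t(apply(pairs, 2, function(ij) replace(numeric(4), ij, 1)))
  w_ls <- as.numeric(solve(crossprod(A), crossprod(A, tvals)))
  rho_ls <- diag(4)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tij <- tvals[k]
    rho_ls[i, j] <- rho_ls[j, i] <-
      max(-1, min(1, (w_ls[i] + w_ls[j] - tij) / (2 * sqrt(w_ls[i] * w_ls[j]))))
  }
  expect_equal(unname(fit$rho), rho_ls, tolerance = 1e-8)
})

test_that("rho is symmetric with unit diagonal, bounded, and deterministic", {
  sim <- null_sim(n_taxa = 12, n_samples = 40, seed = 5, depth = 2000)
  f1 <- sparcc(sim$prok, iterations = 10, seed = 3)
  f2 <- sparcc(sim$prok, iterations = 10, seed = 3)
  expect_identical(f1$rho, f2$rho)
  expect_equal(f1$rho, t(f1$rho))
  expect_equal(unname(diag(f1$rho)), rep(1, 12))
  expect_true(all(abs(f1$rho) <= 1))
  expect_error(sparcc(abund_tbl(data.frame(taxon_id = c("a", "b", "c"),
                                           s1 = 1:3, s2 = 3:1, s3 = 2:4))),
               "more than 3 taxa")
})

test_that("bootstrap p-values respect the estimator bound and detect signal", {
  cfg <- sim_config(n_taxa_prok = 12, n_taxa_euk = 0, n_samples_per_period = 100,
                    periods = "melt", focal_multipliers = 1,
                    qpcr_total_means = 2e8, qpcr_prok_share = 1,
                    keystone_phylum = NULL, sequencing_depth = 5000,
                    correlation_spec = tibble::tibble(
                      taxon_i = "p_zotu_003", taxon_j = "p_zotu_009", rho = 0.85),
                    seed = 4)
  sim <- simulate_communities(cfg)
  fit <- sparcc(sim$prok, iterations = 20, seed = 1)
  fit <- sparcc_bootstrap(sim$prok, fit, n_boot = 99, seed = 1)
  expect_true(all(fit$p >= 1 / 100))
  expect_lte(fit$p["p_zotu_003", "p_zotu_009"], 0.01)
  expect_equal(fit$p, t(fit$p))
})

test_that("network filter keeps exactly the qualifying edges", {
  ids <- paste0("z", 1:4)
  fit <- corr_fixture(
    entries = list(list(1, 2, 0.7), list(1, 3, 0.61), list(1, 4, 0.65),
                   list(2, 3, -0.8)),
    ids = ids,
    p_entries = list(list(1, 2, 0.001), list(1, 3, 0.04), list(1, 4, 0.2),
                     list(2, 3, 0.01)))
  g <- build_network(fit)
  expect_equal(igraph::ecount(g), 3)
  el <- igraph::as_data_frame(g)
  expect_false(any(el$from == "z1" & el$to == "z4" |
                     el$from == "z4" & el$to == "z1"))
  expect_setequal(igraph::E(g)$sign[el$rho < 0], "negative")
  # all p = 1 -> empty network
  fit2 <- corr_fixture(entries = list(list(1, 2, 0.9)), ids = ids,
                       p_entries = list(list(1, 2, 1)))
  expect_equal(igraph::vcount(build_network(fit2)), 0)
  # vacuous filter -> complete graph minus self loops
  set.seed(9)
  rho <- stats::cov2cor(crossprod(matrix(rnorm(36), 9, 4)))
  dimnames(rho) <- list(ids, ids)
  g3 <- build_network(correlation_result(rho), r_threshold = 1e-12,
                      p_threshold = 1)
  expect_equal(igraph::ecount(g3), 6)
})

test_that("network construction is invariant to taxon ordering", {
  set.seed(10)
  rho <- stats::cov2cor(crossprod(matrix(rnorm(60), 10, 6)))
  ids <- paste0("z", 1:6)
  dimnames(rho) <- list(ids, ids)
  g1 <- build_network(correlation_result(rho), r_threshold = 0.3, p_threshold = 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  g2 <- build_network(correlation_result(rho[perm, perm]),
                      r_threshold = 0.3, p_threshold = 1)
  e1 <- igraph::as_data_frame(g1)
  e2 <- igraph::as_data_frame(g2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(e1), key(e2))
})

test_that("topology metrics match hand-enumerated graphs", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  t3 <- network_topology(k3)
  expect_equal(t3$density, 1); expect_equal(t3$clustering, 1)
  expect_equal(t3$avg_path_length, 1); expect_equal(t3$diameter, 1)
  path4 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    directed = FALSE)
  t4 <- network_topology(path4)
  expect_equal(t4$density, 0.5)
  expect_equal(t4$diameter, 3)
  expect_equal(t4$avg_path_length, 5 / 3, tolerance = 1e-12)
  two <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = FALSE)
  t2 <- network_topology(two)
  expect_equal(t2$avg_path_length, 1)
  expect_equal(t2$component_coverage, 0.5)
})

test_that("topology distances standardise metrics and obey the triangle inequality", {
  base <- network_topology(igraph::make_full_graph(4, directed = FALSE) |>
                             (\(g) { igraph::V(g)$name <- paste0("n", 1:4); g })())
  m <- dplyr::bind_rows(base, base, base)
  m$n_nodes <- c(10, 11, 14)    # one metric varies
  d <- as.matrix(topology_distance(m))
  expect_equal(d[1, 2], stats::dist(scale(c(10, 11, 14)))[1], tolerance = 1e-12)
  expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
  expect_equal(d[1, 1], 0)
  expect_error(topology_distance(m[, 1:3]), "missing metric")
})
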
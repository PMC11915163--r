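test_that("Faith PD matches hand sums on the fixture tree", {
  tr <- fixture_tree()
  expect_equal(faith_pd(tr, c("a", "b", "c", "d")), 21)       # whole tree
  expect_equal(faith_pd(tr, "a"), 4)                          # 1 + 3 to root
  expect_equal(faith_pd(tr, c("a", "b")), 6)                  # 1 + 2 + 3
  expect_equal(faith_pd(tr, c("a", "b"), include_root = FALSE), 3)
  expect_warning(pd0 <- faith_pd(tr, character()), "empty")
  expect_equal(pd0, 0)
  # monotone: adding a tip never decreases PD
  expect_gte(faith_pd(tr, c("a", "b", "c")), faith_pd(tr, c("a", "b")))
})

test_that("PD, PSV family and MPD/MNTD agree with the picante oracle", {
  skip_if_not_installed("picante")
  tr <- simulate_phylogeny(16, seed = 3)
  comm <- matrix(0, 2, 16, dimnames = list(c("s1", "s2"), tr$tip.label))
  set.seed(5)
  comm["s1", sample(16, 7)] <- rpois(7, 5) + 1
  comm["s2", sample(16, 9)] <- rpois(9, 5) + 1
  mine_pd <- vapply(rownames(comm), function(s)
    faith_pd(tr, colnames(comm)[comm[s, ] > 0]), numeric(1))
  expect_equal(unname(mine_pd), picante::pd(comm, tr, include.root = TRUE)$PD,
               tolerance = 1e-10)
  pv <- picante::psv(comm, tr); pr <- picante::psr(comm, tr)
  pc <- picante::psc(comm, tr); pe <- picante::pse(comm, tr)
  D <- stats::cophenetic(tr)
  for (s in 1:2) {
    f <- psv_family(tr, comm[s, ])
    expect_equal(f$psv, pv$PSVs[s], tolerance = 1e-10)
    expect_equal(f$psr, pr$PSR[s], tolerance = 1e-10)
    expect_equal(f$psc, pc$PSCs[s], tolerance = 1e-10)
    expect_equal(f$pse, pe$PSEs[s], tolerance = 1e-10)
    obs <- cryocomm:::mpd_mntd(D, colnames(comm)[comm[s, ] > 0])
    expect_equal(unname(obs["mpd"]), picante::mpd(comm, D)[s], tolerance = 1e-10)
    expect_equal(unname(obs["mntd"]), picante::mntd(comm, D)[s], tolerance = 1e-10)
  }
})

test_that("PSV collapses correctly on star and near-duplicate phylogenies", {
  st <- star_tree(5)
  ab <- stats::setNames(rep(1, 5), st$tip.label)
  f <- psv_family(st, ab)
  expect_equal(f$psv, 1)
  expect_equal(f$psr, 5)
  expect_equal(f$psr, f$sr * f$psv)     # exact identity
  # two effectively identical tips: PSV -> 0
  twin <- ape::read.tree(text = "((a:0.0001,b:0.0001):10,c:5);")
  f2 <- psv_family(twin, c(a = 1, b = 1))
  expect_lt(f2$psv, 0.01)
  # PSV invariant to uniform branch scaling
  tr <- fixture_tree()
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7
  ab4 <- stats::setNames(c(1, 2, 3, 4), tr$tip.label)
  expect_equal(psv_family(tr, ab4)$psv, psv_family(tr2, ab4)$psv,
               tolerance = 1e-12)
  # fewer than 2 taxa: undefined-flag
  expect_true(is.na(psv_family(tr, c(a = 1))$psv))
})

test_that("NRI/NTI are deterministic z-scores, positive for clustered tips", {
  tr <- simulate_phylogeny(32, seed = 2)
  D <- stats::cophenetic(tr)
  nt <- D; diag(nt) <- Inf
  ij <- which(nt == min(nt), arr.ind = TRUE)[1, ]
  clustered <- rownames(D)[ij]
  r1 <- nri_nti(tr, clustered, n_null = 199, seed = 1)
  r2 <- nri_nti(tr, clustered, n_null = 199, seed = 1)
  expect_identical(r1, r2)
  expect_gt(r1$nti, 0)
  expect_error(nri_nti(tr, "t1", n_null = 9), ">= 2")
})

test_that("identical communities sit at the betaMNTD minimum with a degenerate null", {
  tr <- simulate_phylogeny(32, seed = 4)
  ab <- stats::setNames(c(rep(2, 8), rep(0, 24)), tr$tip.label)
  r <- beta_nti(tr, ab, ab, n_null = 49, seed = 1)
  expect_equal(r$beta_mntd, 0)
  expect_true(is.na(r$beta_nti))        # sd_null = 0 flagged, not faked
  expect_error(beta_nti(tr, ab, ab * 0), "non-empty")
})

test_that("per-sample phylogenetic metrics table is complete and coherent", {
  sim <- null_sim(n_taxa = 24, n_samples = 6, seed = 3, depth = 300)
  pm <- phylo_community_metrics(sim$prok, sim$tree_prok, n_null = 49, seed = 1)
  expect_identical(nrow(pm), 6L)
  expect_true(all(c("pd", "sr", "psv", "psc", "psr", "pse", "mpd", "mntd",
                    "nri", "nti") %in% names(pm)))
  expect_equal(pm$psr, pm$sr * pm$psv, tolerance = 1e-12)
  expect_true(all(pm$psv >= 0 & pm$psv <= 1, na.rm = TRUE))
  expect_true(all(pm$pse >= 0 & pm$pse <= 1, na.rm = TRUE))
  expect_true(all(pm$pd > 0))
})
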
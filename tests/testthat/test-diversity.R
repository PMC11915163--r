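test_that("alpha diversity matches closed forms", {
  tbl <- abund_tbl(data.frame(taxon_id = paste0("z", 1:4),
                              uniform = c(25, 25, 25, 25),
                              single = c(7, 0, 0, 0),
                              mix = c(1, 2, 3, 0)))
  a <- alpha_diversity(tbl)
  expect_equal(a$shannon[a$sample_id == "uniform"], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[a$sample_id == "single"], 0, tolerance = 1e-12)
  expect_equal(a$shannon[a$sample_id == "mix"],
               -sum(c(1, 2, 3) / 6 * log(c(1, 2, 3) / 6)), tolerance = 1e-9)
  expect_equal(a$shannon[a$sample_id == "mix"], 1.01140, tolerance = 1e-5)
  u5 <- abund_tbl(data.frame(taxon_id = paste0("z", 1:5), s = rep(9, 5)))
  expect_equal(alpha_diversity(u5)$gini_simpson, 0.8, tolerance = 1e-12)
  two <- abund_tbl(data.frame(taxon_id = c("a", "b"), s = c(1, 3)))
  expect_equal(alpha_diversity(two)$gini_simpson, 0.375, tolerance = 1e-12)
})

test_that("distances satisfy identity, bounds and the Sørensen closed form", {
  tbl <- abund_tbl(data.frame(taxon_id = paste0("z", 1:4),
                              s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1),
                              s3 = c(1, 1, 1, 0)))
  ds <- community_distance(tbl, "sorensen")
  m <- as.matrix(ds)
  expect_equal(m["s1", "s2"], 1 / 3, tolerance = 1e-12)  # 1 - 4/6
  expect_equal(m["s1", "s3"], 0)
  db <- as.matrix(community_distance(tbl, "bray_curtis"))
  expect_true(all(db >= 0 & db <= 1))
  expect_equal(unname(diag(db)), rep(0, 3))
  disj <- abund_tbl(data.frame(taxon_id = c("a", "b"), s1 = c(2, 0), s2 = c(0, 3)))
  expect_equal(as.matrix(community_distance(disj, "bray_curtis"))["s1", "s2"], 1)
  expect_equal(as.matrix(community_distance(disj, "sorensen"))["s1", "s2"], 1)
})

test_that("PCA has non-increasing variance proportions summing to 1", {
  set.seed(1)
  tbl <- abund_from_matrix(matrix(rpois(50, 20), 10, 5,
                                  dimnames = list(paste0("z", 1:10),
                                                  paste0("s", 1:5))))
  pc <- pca_ordination(tbl)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # rank-1 data: all variance on axis 1 (raw transform keeps collinearity)
  line <- outer(c(1, 2, 3, 4), c(1, 2, 3))
  dimnames(line) <- list(paste0("z", 1:4), paste0("s", 1:3))
  pc1 <- pca_ordination(abund_from_matrix(line), transform = "raw")
  expect_equal(pc1$var_explained[1], 1, tolerance = 1e-9)
  # identical samples flagged degenerate
  same <- abund_from_matrix(matrix(c(3, 1, 3, 1), 2, 2,
                                   dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_true(pca_ordination(same)$degenerate)
})

test_that("PERMANOVA separates true clusters and not copies", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40), 10, 4), matrix(rnorm(40, mean = 5), 10, 4))
  rownames(x) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(stats::dist(x), g, n_perm = 199, seed = 1)
  expect_lte(res$p_value, 0.005)
  expect_gt(res$r_squared, 0.5)
  # copied groups: no between-group structure
  x2 <- rbind(x[1:10, ], x[1:10, ])
  res2 <- permanova(stats::dist(x2), g, n_perm = 99, seed = 1)
  expect_lt(abs(res2$r_squared), 1e-9)
})

test_that("Procrustes m2 is invariant to similarity transforms and localises error", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3 * X %*% R + matrix(c(2, -7), 20, 2, byrow = TRUE)
  rownames(Y) <- rownames(X)
  pr <- procrustes_concordance(X, Y, n_perm = 99, seed = 1)
  expect_lt(pr$m2, 1e-10)
  expect_lt(max(pr$residuals), 1e-6)
  Y2 <- X
  Y2["s7", ] <- Y2["s7", ] + 5
  pr2 <- procrustes_concordance(X, Y2, n_perm = 99, seed = 1)
  expect_identical(names(which.max(pr2$residuals)), "s7")
  expect_error(procrustes_concordance(X, Y[1:10, ]), "mismatch")
})

test_that("turnover follows the gained/lost/shared contract", {
  ids <- paste0("z", 1:4)
  tax <- tiny_taxonomy(ids, phylum = rep("P", 4))
  ta <- abund_tbl(data.frame(taxon_id = ids, s1 = c(1, 1, 1, 0)))
  tb <- abund_tbl(data.frame(taxon_id = ids, s1 = c(0, 1, 1, 1)))
  tv <- turnover(ta, tb, tax)
  expect_equal(tv$rate, 0.5)     # (1 gained + 1 lost) / 4
  expect_equal(tv$gained, 1L); expect_equal(tv$lost, 1L); expect_equal(tv$shared, 2L)
  expect_equal(turnover(ta, ta, tax)$rate, 0)
  tc <- abund_tbl(data.frame(taxon_id = ids, s1 = c(0, 0, 0, 1)))
  td <- abund_tbl(data.frame(taxon_id = ids, s1 = c(1, 1, 0, 0)))
  expect_equal(turnover(tc, td, tax)$rate, 1)
  # phylum absent from both -> NA
  tax2 <- tiny_taxonomy(ids, phylum = c("P", "P", "P", "Q"))
  te <- abund_tbl(data.frame(taxon_id = ids, s1 = c(1, 1, 0, 0)))
  tv2 <- turnover(te, te, tax2)
  expect_true(is.na(tv2$rate[tv2$label == "Q"]))
})

test_that("venn partition enumerates the 7 regions and sums to the union", {
  vp <- venn_partition(list(a = c("1", "2", "3"), b = c("2", "3", "4"),
                            c = c("3", "4", "5")))
  expect_identical(vp$count, c(1L, 0L, 1L, 1L, 0L, 1L, 1L))
  expect_identical(sum(vp$count), 5L)
  eq <- venn_partition(list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y")))
  expect_identical(eq$count[eq$region == "a&b&c"], 2L)
  expect_identical(sum(eq$count), 2L)
  dis <- venn_partition(list(a = "1", b = "2", c = "3"))
  expect_identical(dis$count, c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
})
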
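#' Per-sample alpha diversity
#'
#' Shannon index `H = -sum p_i log p_i` (natural log) and Gini-Simpson
#' index `1 - sum p_i^2`, via the standard vegan estimators, plus observed
#' richness.
#'
#' @param x An [abund_tbl()].
#' @return A tibble `sample_id`, `richness`, `shannon`, `gini_simpson`.
#' @export
alpha_diversity <- function(x) {
  m <- t(abund_matrix(x))
  if (any(rowSums(m) <= 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    sample_id = rownames(m),
    richness = rowSums(m > 0),
    shannon = as.numeric(vegan::diversity(m, index = "shannon")),
    gini_simpson = as.numeric(vegan::diversity(m, index = "simpson"))
  )
}

#' Pairwise period comparisons of alpha diversity
#'
#' Two-sided Welch t-tests between all period pairs for each index, with
#' Benjamini-Hochberg FDR correction across all comparisons.
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Tibble `sample_id`, `period`.
#' @return A tibble `index`, `period_a`, `period_b`, `estimate` (mean
#'   difference a - b), `p_value`, `p_adjusted`.
#' @export
alpha_diversity_tests <- function(alpha, metadata) {
  dat <- dplyr::inner_join(alpha, metadata, by = "sample_id")
  periods <- levels(droplevels(factor(dat$period)))
  idx <- c("shannon", "gini_simpson")
  out <- list()
  for (ix in idx) {
    for (a in seq_along(periods)) {
      for (b in seq_along(periods)) {
        if (b <= a) next
        xa <- dat[[ix]][dat$period == periods[a]]
        xb <- dat[[ix]][dat$period == periods[b]]
        tt <- stats::t.test(xa, xb)
        out[[length(out) + 1L]] <- tibble::tibble(
          index = ix, period_a = periods[a], period_b = periods[b],
          estimate = mean(xa) - mean(xb), p_value = tt$p.value)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$p_adjusted <- bh_adjust(res$p_value)
  res
}

#' Between-sample community distances
#'
#' Bray-Curtis (`sum |x - y| / sum (x + y)`), Sørensen
#' (`1 - 2|A ∩ B| / (|A| + |B|)`, i.e. presence/absence Bray-Curtis) or
#' Euclidean distance between sample columns.
#'
#' @param x An [abund_tbl()].
#' @param metric `"bray_curtis"`, `"sorensen"` or `"euclidean"`.
#' @return A `dist` over samples with a `metric` attribute.
#' @export
community_distance <- function(x, metric = c("bray_curtis", "sorensen",
                                             "euclidean")) {
  metric <- match.arg(metric)
  m <- t(abund_matrix(x))
  if (metric != "euclidean" && sum(rowSums(m) == 0) >= 2) {
    stop("distance undefined between two all-zero samples", call. = FALSE)
  }
  d <- switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    sorensen = vegan::vegdist(m, method = "bray", binary = TRUE),
    euclidean = stats::dist(m))
  attr(d, "metric") <- metric
  d
}

#' Principal components ordination of community profiles
#'
#' Eigendecomposition of the covariance of column-centred sample profiles,
#' by default after Hellinger transformation of relative abundances. Axis
#' signs are fixed so that the largest-magnitude taxon loading on each axis
#' is positive.
#'
#' @param x An [abund_tbl()].
#' @param transform `"hellinger"` (default), `"raw"` or `"clr"` (centred
#'   log-ratio with a 0.5 pseudocount on zeros).
#' @return A list of class `pca_ordination` with `scores` (tibble
#'   `sample_id`, `PC1`, ...), `var_explained` (proportions, sum 1) and
#'   `degenerate` (TRUE when total variance is zero).
#' @export
pca_ordination <- function(x, transform = c("hellinger", "raw", "clr")) {
  transform <- match.arg(transform)
  m <- t(abund_matrix(x))                       # samples x taxa
  if (nrow(m) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  m <- switch(transform,
    hellinger = {
      h <- suppressWarnings(vegan::decostand(m, method = "hellinger"))
      h[rowSums(m) == 0, ] <- 0              # empty samples stay at origin
      h
    },
    raw = m,
    clr = {
      mm <- m
      mm[mm == 0] <- 0.5
      lm_ <- log(mm)
      sweep(lm_, 1L, rowMeans(lm_), "-")
    })
  ctr <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(ctr^2)
  if (total_var < 1e-12) {
    k <- min(2L, ncol(m))
    scores <- matrix(0, nrow(m), k,
                     dimnames = list(rownames(m), paste0("PC", seq_len(k))))
    return(structure(list(
      scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                                tibble::as_tibble(scores)),
      var_explained = rep(NA_real_, k), degenerate = TRUE,
      transform = transform), class = "pca_ordination"))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  # sign convention: largest |loading| positive per axis
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(pc$x)),
                              tibble::as_tibble(pc$x)),
    var_explained = ve, degenerate = FALSE, transform = transform),
    class = "pca_ordination")
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's permutational MANOVA (vegan `adonis2`): partitions the sum of
#' squared distances between and within groups; the permutation p-value
#' uses the `(1 + m) / (1 + M)` estimator.
#'
#' @param d A `dist` (e.g. from [community_distance()]).
#' @param groups Group label per sample, in `d`'s sample order.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble `r_squared`, `f_statistic`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  set.seed(seed)
  dat <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = dat, permutations = n_perm)
  tibble::tibble(r_squared = fit$R2[1], f_statistic = fit$F[1],
                 p_value = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' Procrustes concordance of two ordinations
#'
#' Symmetric Procrustes superimposition (translation, rotation, uniform
#' scaling minimising the sum of squared distances); `m2` is the symmetric
#' Procrustes statistic in [0, 1], with a permutation p-value from
#' row-permutations of the second configuration (vegan `protest`).
#'
#' @param x,y Sample coordinate matrices (or `pca_ordination` objects)
#'   over the same samples.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list of class `procrustes_concordance`: `m2`, `residuals`
#'   (named per sample), `p_value`, `n_perm`.
#' @export
procrustes_concordance <- function(x, y, n_perm = 999, seed = 1) {
  as_coords <- function(z) {
    if (inherits(z, "pca_ordination")) {
      m <- as.matrix(z$scores[-1])
      rownames(m) <- z$scores$sample_id
      m
    } else as.matrix(z)
  }
  X <- as_coords(x); Y <- as_coords(y)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y))) {
      stop("mismatched samples between configurations", call. = FALSE)
    }
    Y <- Y[rownames(X), , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("mismatched samples between configurations", call. = FALSE)
  }
  set.seed(seed)
  pt <- vegan::protest(X, Y, permutations = n_perm, symmetric = TRUE)
  res <- stats::residuals(pt)
  structure(list(m2 = unname(pt$ss), residuals = res,
                 correlation = unname(pt$t0),
                 p_value = unname(pt$signif), n_perm = n_perm),
            class = "procrustes_concordance")
}

# Pooled presence (count > 0 in any sample of the group) per taxon.
pooled_presence <- function(x, metadata = NULL) {
  m <- abund_matrix(x)
  if (is.null(metadata)) return(rowSums(m) > 0)
  groups <- split(metadata$sample_id, metadata$period)
  vapply(groups, function(s) rowSums(m[, s, drop = FALSE]) > 0,
         logical(nrow(m)))
}

#' Per-phylum turnover between two pooled periods
#'
#' Samples of each period are pooled to presence/absence; per phylum the
#' taxa gained, lost and shared between periods give the turnover rate
#' `(gained + lost) / (gained + lost + shared)` — the fraction of the
#' pooled union that changed (the Jaccard dissimilarity of the two pooled
#' presence sets).
#'
#' @param xa,xb [abund_tbl()]s for the two periods (same taxon universe).
#' @param taxonomy Taxonomy tibble.
#' @param rank Rank at which to group taxa.
#' @return A tibble `label`, `gained`, `lost`, `shared`, `rate` (`NA` when
#'   the group is absent from both periods).
#' @export
turnover <- function(xa, xb, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, tax_ranks())
  universe <- union(xa$taxon_id, xb$taxon_id)
  miss <- setdiff(universe, taxonomy$taxon_id)
  if (length(miss)) stop("taxa missing from taxonomy: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pa <- universe %in% xa$taxon_id[rowSums(abund_matrix(xa)) > 0]
  pb <- universe %in% xb$taxon_id[rowSums(abund_matrix(xb)) > 0]
  lab <- taxonomy[[rank]][match(universe, taxonomy$taxon_id)]
  tibble::tibble(label = lab, a = pa, b = pb) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      gained = sum(!.data$a & .data$b),
      lost = sum(.data$a & !.data$b),
      shared = sum(.data$a & .data$b), .groups = "drop") |>
    dplyr::mutate(rate = ifelse(.data$gained + .data$lost + .data$shared == 0,
                                NA_real_,
                                (.data$gained + .data$lost) /
                                  (.data$gained + .data$lost + .data$shared)))
}

#' Seven-region Venn partition of three presence sets
#'
#' @param sets A named list of three character vectors (taxon ids present
#'   in each period).
#' @return A tibble `region`, `count`; counts sum to the size of the union.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3)
  nm <- names(sets) %||% c("A", "B", "C")
  u <- unique(unlist(sets))
  inA <- u %in% sets[[1]]; inB <- u %in% sets[[2]]; inC <- u %in% sets[[3]]
  tibble::tibble(
    region = c(nm[1], nm[2], nm[3],
               paste(nm[1], nm[2], sep = "&"),
               paste(nm[1], nm[3], sep = "&"),
               paste(nm[2], nm[3], sep = "&"),
               paste(nm, collapse = "&")),
    count = c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
              sum(!inA & !inB & inC), sum(inA & inB & !inC),
              sum(inA & !inB & inC), sum(!inA & inB & inC),
              sum(inA & inB & inC)))
}
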
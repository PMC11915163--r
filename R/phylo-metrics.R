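#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the present tips;
#' by default the path to the root is included, so a single-tip community
#' has PD equal to its root-to-tip distance.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param taxa Character vector of present tip labels.
#' @param include_root Include branches on the path from the spanning
#'   subtree to the root (default `TRUE`).
#' @return PD (0 for an empty set, with a warning).
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  taxa <- intersect(taxa, tree$tip.label)
  if (length(taxa) == 0L) {
    warning("empty community: PD = 0")
    return(0)
  }
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n_tip + 1L
  marked <- logical(n_tip + tree$Nnode)
  for (tip in match(taxa, tree$tip.label)) {
    v <- tip
    while (v != root && !marked[v]) {
      marked[v] <- TRUE
      v <- parent[v]
    }
  }
  if (!include_root && length(taxa) >= 2L) {
    # unmark the chain of nodes ancestral to the MRCA of the set
    mrca <- if (length(taxa) == n_tip) root else
      ape::getMRCA(tree, taxa)
    v <- mrca
    while (v != root) {
      marked[v] <- FALSE
      v <- parent[v]
    }
  }
  sum(elen[marked])
}

# Phylogenetic correlation matrix (shared path length to root, unit diag).
phylo_corr <- function(tree) ape::vcv(tree, corr = TRUE)

#' PSV family of phylogenetic community metrics
#'
#' Helmus et al. definitions on the phylogenetic correlation matrix `C`
#' (shared branch length to the root, scaled to unit diagonal):
#' `PSV = (n tr(C) - sum(C)) / (n (n - 1))` over the community submatrix,
#' `PSR = n PSV`, `PSC = 1 - mean_i max_{j != i} C_ij`, and the
#' abundance-weighted `PSE = (M sum_i c_ii m_i - m' C m) / (M^2 - M mbar)`
#' with abundances `m`, total `M` and mean `mbar`.
#'
#' @param tree A rooted [ape::phylo].
#' @param abundance Named numeric vector of abundances (names = tip
#'   labels); presence/absence works for PSV/PSC/PSR.
#' @param C Optional precomputed correlation matrix (from repeated calls).
#' @return A one-row tibble `sr`, `psv`, `psc`, `psr`, `pse` (`NA` for
#'   PSV/PSC/PSR/PSE when fewer than 2 taxa are present).
#' @export
psv_family <- function(tree, abundance, C = NULL) {
  abundance <- abundance[abundance > 0]
  ids <- intersect(names(abundance), if (is.null(C)) tree$tip.label else rownames(C))
  n <- length(ids)
  if (n < 2L) {
    return(tibble::tibble(sr = n, psv = NA_real_, psc = NA_real_,
                          psr = NA_real_, pse = NA_real_))
  }
  if (is.null(C)) C <- phylo_corr(tree)
  Cs <- C[ids, ids]
  psv <- (n * sum(diag(Cs)) - sum(Cs)) / (n * (n - 1))
  offdiag <- Cs; diag(offdiag) <- -Inf
  psc <- 1 - mean(apply(offdiag, 1L, max))
  m <- as.numeric(abundance[ids])
  M <- sum(m)
  # Helmus abundance-weighted PSV: (M sum(c_ii m_i) - m'Cm) / (M^2 - M mbar)
  pse <- (M * sum(diag(Cs) * m) - as.numeric(t(m) %*% Cs %*% m)) /
    (M^2 - M * mean(m))
  tibble::tibble(sr = n, psv = psv, psc = psc, psr = n * psv, pse = pse)
}

# Mean pairwise and mean nearest-taxon patristic distance for a community
# given the full cophenetic matrix.
mpd_mntd <- function(D, ids, abundance = NULL) {
  Ds <- D[ids, ids, drop = FALSE]
  n <- length(ids)
  if (n < 2L) return(c(mpd = NA_real_, mntd = NA_real_))
  off <- Ds[upper.tri(Ds)]
  nt <- Ds; diag(nt) <- Inf
  nearest <- row_mins(nt)
  if (is.null(abundance)) {
    c(mpd = mean(off), mntd = mean(nearest))
  } else {
    w <- abundance[ids] / sum(abundance[ids])
    W <- outer(w, w)
    diag(W) <- 0
    c(mpd = sum(W * Ds) / sum(W), mntd = sum(w * nearest))
  }
}

#' Net relatedness and nearest taxon indices
#'
#' `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)` and NTI analogously
#' with the mean nearest-taxon distance; the null shuffles tip labels
#' across the full taxon pool, so positive values indicate phylogenetic
#' clustering.
#'
#' @param tree A rooted [ape::phylo] (or `NULL` when `D` is given).
#' @param taxa Present tip labels (>= 2).
#' @param n_null Number of null randomisations.
#' @param seed Integer seed.
#' @param D Optional precomputed cophenetic distance matrix over the pool.
#' @param pool Taxon pool for the shuffle (defaults to all rows of `D`).
#' @return A one-row tibble `mpd`, `mntd`, `nri`, `nti` (`NA` z-scores if a
#'   null sd is 0).
#' @export
nri_nti <- function(tree, taxa, n_null = 999, seed = 1, D = NULL,
                    pool = NULL) {
  if (is.null(D)) D <- stats::cophenetic(tree)
  if (is.null(pool)) pool <- rownames(D)
  taxa <- intersect(taxa, pool)
  if (length(taxa) < 2L) stop("community must contain >= 2 pool taxa", call. = FALSE)
  obs <- mpd_mntd(D, taxa)
  k <- length(taxa)
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    mpd_mntd(D, sample(pool, k))
  }, numeric(2))
  z <- function(o, null_v) {
    s <- stats::sd(null_v)
    if (!is.finite(s) || s == 0) return(NA_real_)
    -(o - mean(null_v)) / s
  }
  tibble::tibble(mpd = unname(obs["mpd"]), mntd = unname(obs["mntd"]),
                 nri = unname(z(obs["mpd"], nulls[1, ])),
                 nti = unname(z(obs["mntd"], nulls[2, ])))
}

# Between-community mean nearest taxon distance, optionally abundance
# weighted: mean over taxa of the distance to the nearest taxon in the
# other community, averaged over both directions.
beta_mntd <- function(D, a, b, weighted = TRUE) {
  ia <- names(a)[a > 0]; ib <- names(b)[b > 0]
  da <- row_mins(D[ia, ib, drop = FALSE])
  db <- row_mins(D[ib, ia, drop = FALSE])
  if (weighted) {
    wa <- a[ia] / sum(a[ia]); wb <- b[ib] / sum(b[ib])
    (sum(wa * da) + sum(wb * db)) / 2
  } else {
    (mean(da) + mean(db)) / 2
  }
}

#' Beta nearest taxon index for a pair of communities
#'
#' Standardised deviation of the observed between-community mean nearest
#' taxon distance from a tip-shuffle null:
#' `betaNTI = (bMNTD_obs - mean(bMNTD_null)) / sd(bMNTD_null)`.
#' |betaNTI| > 2 is conventionally read as deterministic assembly.
#'
#' @param tree A rooted [ape::phylo] (or `NULL` when `D` is given).
#' @param a,b Named abundance vectors for the two communities.
#' @param n_null Number of tip shuffles.
#' @param seed Integer seed.
#' @param weighted Abundance-weighted (default) or presence/absence.
#' @param D Optional precomputed cophenetic matrix.
#' @return A one-row tibble `beta_mntd`, `null_mean`, `null_sd`,
#'   `beta_nti`, `n_null`.
#' @export
beta_nti <- function(tree, a, b, n_null = 999, seed = 1, weighted = TRUE,
                     D = NULL) {
  if (is.null(D)) D <- stats::cophenetic(tree)
  a <- a[a > 0]; b <- b[b > 0]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both communities must be non-empty", call. = FALSE)
  }
  obs <- beta_mntd(D, a, b, weighted)
  pool <- rownames(D)
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    perm <- sample(pool)
    Dp <- D
    dimnames(Dp) <- list(perm, perm)
    beta_mntd(Dp, a, b, weighted)
  }, numeric(1))
  s <- stats::sd(nulls)
  tibble::tibble(beta_mntd = obs, null_mean = mean(nulls), null_sd = s,
                 beta_nti = if (s > 0) (obs - mean(nulls)) / s else NA_real_,
                 n_null = n_null)
}

#' Pairwise betaNTI over the samples of a count table
#'
#' @param x An [abund_tbl()] restricted to tips of `tree`.
#' @param tree A rooted [ape::phylo].
#' @inheritParams beta_nti
#' @return A tibble `sample_a`, `sample_b`, `beta_mntd`, `beta_nti`.
#' @export
beta_nti_matrix <- function(x, tree, n_null = 999, seed = 1, weighted = TRUE) {
  m <- abund_matrix(x)
  keep <- intersect(rownames(m), tree$tip.label)
  m <- m[keep, , drop = FALSE]
  D <- stats::cophenetic(tree)[keep, keep]
  samples <- colnames(m)
  out <- list()
  k <- 0L
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j <= i) next
      k <- k + 1L
      r <- beta_nti(NULL, m[, i], m[, j], n_null = n_null,
                    seed = substream_seed(seed, k), weighted = weighted,
                    D = D)
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(sample_a = samples[i], sample_b = samples[j]), r)
    }
  }
  dplyr::bind_rows(out)
}

#' Per-sample phylogenetic community structure
#'
#' Computes PD, SR, the PSV family, MPD/MNTD and NRI/NTI for every sample
#' of a count table against one tree.
#'
#' @param x An [abund_tbl()].
#' @param tree A rooted [ape::phylo] covering (a superset of) the taxa.
#' @param n_null Null randomisations for NRI/NTI.
#' @param seed Integer seed.
#' @param include_root Passed to [faith_pd()].
#' @return A tibble with one row per sample.
#' @export
phylo_community_metrics <- function(x, tree, n_null = 999, seed = 1,
                                    include_root = TRUE) {
  m <- abund_matrix(x)
  keep <- intersect(rownames(m), tree$tip.label)
  m <- m[keep, , drop = FALSE]
  C <- phylo_corr(tree)
  D <- stats::cophenetic(tree)[keep, keep]
  purrr::imap_dfr(
    stats::setNames(seq_len(ncol(m)), colnames(m)),
    function(j, sid) {
      ab <- m[, j]
      present <- names(ab)[ab > 0]
      base <- tibble::tibble(sample_id = sid,
                             pd = faith_pd(tree, present, include_root))
      fam <- psv_family(tree, ab, C = C)
      zz <- if (length(present) >= 2) {
        nri_nti(NULL, present, n_null = n_null,
                seed = substream_seed(seed, j), D = D, pool = keep)
      } else {
        tibble::tibble(mpd = NA_real_, mntd = NA_real_,
                       nri = NA_real_, nti = NA_real_)
      }
      dplyr::bind_cols(base, fam, zz)
    })
}
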
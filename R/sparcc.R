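#' SparCC compositional correlation inference
#'
#' Estimates basis correlations between taxa from compositional count data.
#' Each iteration draws per-sample fractions from the Dirichlet posterior
#' with a unit prior (or uses deterministic `(count + 1)` fractions),
#' computes the matrix of log-ratio variances
#' `t_ij = var(log(x_i / x_j))`, solves the linear system
#' `t_i = (D - 2) w_i + sum_j w_j` for the basis variances `w` under the
#' sparsity assumption, and forms
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` clipped to [-1, 1].
#' Strongly correlated pairs are iteratively excluded from the system
#' (up to `exclusion_rounds` passes removing the largest |rho| pair above
#' `exclusion_threshold`) and the final estimate is the element-wise median
#' over iterations.
#'
#' @param x An [abund_tbl()] of counts (>= 4 taxa, >= 3 samples).
#' @param iterations Number of resampled iterations.
#' @param exclusion_rounds Maximum strongly-correlated-pair exclusions.
#' @param exclusion_threshold |rho| above which a pair may be excluded.
#' @param seed Integer seed for the Dirichlet draws.
#' @param fraction_method `"dirichlet"` (default) or the deterministic
#'   `"pseudocount"` mode for reproducible unit testing.
#' @return A list of class `sparcc_result`: `taxon_ids`, `rho`
#'   (symmetric, unit diagonal), `p` (`NULL` until
#'   [sparcc_bootstrap()]), and `settings`.
#' @export
sparcc <- function(x, iterations = 50, exclusion_rounds = 10,
                   exclusion_threshold = 0.1, seed = 1,
                   fraction_method = c("dirichlet", "pseudocount")) {
  fraction_method <- match.arg(fraction_method)
  m <- t(abund_matrix(x))                       # samples x taxa
  d <- ncol(m)
  if (d <= 3L) stop("SparCC needs more than 3 taxa", call. = FALSE)
  if (nrow(m) < 3L) stop("SparCC needs at least 3 samples", call. = FALSE)
  if (any(apply(m, 2L, stats::sd) == 0) && fraction_method == "pseudocount") {
    # all-equal columns give zero log-ratio variance rows; flag degenerate
    if (all(apply(m, 2L, stats::sd) == 0)) {
      stop("degenerate input: all columns constant", call. = FALSE)
    }
  }
  set.seed(seed)
  n_iter <- if (fraction_method == "pseudocount") 1L else iterations
  rhos <- array(NA_real_, dim = c(d, d, n_iter))
  for (it in seq_len(n_iter)) {
    fr <- if (fraction_method == "pseudocount") {
      f <- m + 1
      f / rowSums(f)
    } else {
      rdirichlet_rows(m)
    }
    lf <- log(fr)
    V <- stats::cov(lf)
    vl <- diag(V)
    Tm <- outer(vl, vl, "+") - 2 * V            # log-ratio variance matrix
    rhos[, , it] <- sparcc_basis_rho(Tm, exclusion_rounds, exclusion_threshold)
  }
  rho <- apply(rhos, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  structure(list(taxon_ids = colnames(m), rho = rho, p = NULL,
                 settings = list(iterations = iterations,
                                 exclusion_rounds = exclusion_rounds,
                                 exclusion_threshold = exclusion_threshold,
                                 seed = seed,
                                 fraction_method = fraction_method)),
            class = "sparcc_result")
}

# Basis-variance solve + correlation matrix for one log-ratio variance
# matrix, with iterative exclusion of strongly correlated pairs.
sparcc_basis_rho <- function(Tm, exclusion_rounds, exclusion_threshold) {
  d <- nrow(Tm)
  M <- matrix(1, d, d)
  diag(M) <- d - 1
  t_vec <- rowSums(Tm)
  excluded <- matrix(FALSE, d, d)
  rho_from <- function(w) {
    w <- pmax(w, 1e-12)
    r <- (outer(w, rep(1, d)) + outer(rep(1, d), w) - Tm) /
      (2 * sqrt(outer(w, w)))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  w <- solve(M, t_vec)
  rho <- rho_from(w)
  for (round in seq_len(exclusion_rounds)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    # a taxon must keep at least 3 partners in the system
    deg <- diag(M)
    low <- deg <= 3
    cand[low, ] <- 0
    cand[, low] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    t_vec[i] <- t_vec[i] - Tm[i, j]
    t_vec[j] <- t_vec[j] - Tm[i, j]
    w <- solve(M, t_vec)
    rho <- rho_from(w)
  }
  rho
}

#' Bootstrap p-values for SparCC correlations
#'
#' Each bootstrap dataset resamples every taxon's counts independently with
#' replacement across samples (destroying inter-taxon association while
#' preserving marginals), recomputes the SparCC correlation matrix, and the
#' two-sided p-value for each pair is
#' `(1 + #{|rho_boot| >= |rho_obs|}) / (1 + n_boot)`.
#'
#' @param x The same [abund_tbl()] used for the observed fit.
#' @param fit A `sparcc_result` from [sparcc()] on `x`.
#' @param n_boot Number of bootstrap datasets.
#' @param seed Integer seed.
#' @param iterations SparCC iterations per bootstrap (defaults to the
#'   observed fit's setting).
#' @return `fit` with its `p` matrix filled in and `n_bootstrap` recorded.
#' @export
sparcc_bootstrap <- function(x, fit, n_boot = 999, seed = 1,
                             iterations = NULL) {
  stopifnot(inherits(fit, "sparcc_result"))
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  m <- abund_matrix(x)                          # taxa x samples
  stopifnot(identical(rownames(m), fit$taxon_ids))
  iterations <- iterations %||% fit$settings$iterations
  n_s <- ncol(m)
  abs_obs <- abs(fit$rho)
  exceed <- matrix(0L, nrow(m), nrow(m))
  for (b in seq_len(n_boot)) {
    bseed <- substream_seed(seed, b)
    set.seed(bseed)
    mb <- t(vapply(seq_len(nrow(m)),
                   function(i) m[i, sample.int(n_s, n_s, replace = TRUE)],
                   numeric(n_s)))
    dimnames(mb) <- dimnames(m)
    fb <- sparcc(abund_from_matrix(mb, unit = abund_unit(x)),
                 iterations = iterations,
                 exclusion_rounds = fit$settings$exclusion_rounds,
                 exclusion_threshold = fit$settings$exclusion_threshold,
                 seed = substream_seed(bseed, 1),
                 fraction_method = fit$settings$fraction_method)
    exceed <- exceed + (abs(fb$rho) >= abs_obs)
  }
  p <- (1 + exceed) / (1 + n_boot)
  diag(p) <- 1
  dimnames(p) <- dimnames(fit$rho)
  fit$p <- p
  fit$n_bootstrap <- n_boot
  fit$settings$bootstrap_seed <- seed
  fit
}

#' Construct a sparcc_result from given matrices
#'
#' Mostly useful for tests and for feeding externally computed correlation
#' and p-value matrices into the network/cohesion machinery.
#'
#' @param rho Symmetric correlation matrix with unit diagonal and taxon
#'   dimnames.
#' @param p Optional matching p-value matrix.
#' @return A `sparcc_result`.
#' @export
correlation_result <- function(rho, p = NULL) {
  stopifnot(is.matrix(rho), !is.null(rownames(rho)),
            isTRUE(all.equal(rho, t(rho), tolerance = 1e-8)),
            all(abs(diag(rho) - 1) < 1e-8), all(abs(rho) <= 1 + 1e-12))
  if (!is.null(p)) {
    stopifnot(identical(dim(p), dim(rho)), all(p >= 0 & p <= 1))
    dimnames(p) <- dimnames(rho)
  }
  structure(list(taxon_ids = rownames(rho), rho = rho, p = p,
                 settings = list(source = "external")),
            class = "sparcc_result")
}

#' Build a filtered co-occurrence network
#'
#' Keeps an edge between taxa i and j iff `|rho_ij| > r_threshold` and
#' `p_ij <= p_threshold`; isolated nodes are dropped. Edge weights carry
#' the signed correlation.
#'
#' @param fit A `sparcc_result` (with `p` filled unless `p` is `NULL`, in
#'   which case only the correlation filter applies).
#' @param r_threshold Correlation magnitude threshold (default 0.6).
#' @param p_threshold p-value threshold (default 0.05).
#' @param taxonomy Optional taxonomy tibble; adds a `phylum` vertex
#'   attribute.
#' @return An [igraph::graph] with vertex attribute `name` (+ `phylum`)
#'   and edge attributes `weight` (signed rho), `rho`, `p`, `sign`.
#' @export
build_network <- function(fit, r_threshold = 0.6, p_threshold = 0.05,
                          taxonomy = NULL) {
  stopifnot(inherits(fit, "sparcc_result"))
  rho <- fit$rho
  keep <- abs(rho) > r_threshold
  if (!is.null(fit$p)) keep <- keep & (fit$p <= p_threshold)
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(rho)[idx[, 1]],
    to = colnames(rho)[idx[, 2]],
    rho = rho[idx],
    p = if (!is.null(fit$p)) fit$p[idx] else NA_real_)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = fit$taxon_ids))
  igraph::E(g)$weight <- edges$rho
  igraph::E(g)$sign <- ifelse(edges$rho > 0, "positive", "negative")
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (!is.null(taxonomy)) {
    igraph::V(g)$phylum <-
      taxonomy$phylum[match(igraph::V(g)$name, taxonomy$taxon_id)]
  }
  g$r_threshold <- r_threshold
  g$p_threshold <- p_threshold
  g
}

#' Topology of a co-occurrence network
#'
#' Standard unweighted indices on the undirected simple graph: node and
#' edge counts, mean degree, density `2E / (N (N - 1))`, global clustering
#' coefficient, average path length and diameter on the largest connected
#' component (with the covered fraction reported), and the modularity of
#' the greedy partition from [detect_modules()].
#'
#' @param g An igraph network from [build_network()].
#' @return A one-row tibble of topology metrics.
#' @export
network_topology <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  part <- detect_modules(g)
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = mean(igraph::degree(g)),
    density = igraph::edge_density(g),
    clustering = igraph::transitivity(g, type = "global"),
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    diameter = igraph::diameter(giant, weights = NA),
    modularity = part$modularity,
    n_modules = length(unique(part$membership$module)),
    component_coverage = max(comp$csize) / igraph::vcount(g))
}

#' Euclidean distance between standardised network topology profiles
#'
#' Each metric is z-scored across the networks before computing pairwise
#' Euclidean distances, so no single index dominates by scale.
#'
#' @param metrics A list (or row-bound tibble) of [network_topology()]
#'   rows, one per network.
#' @param columns Metrics to use (defaults to all shared numeric columns).
#' @return A `dist` over networks.
#' @export
topology_distance <- function(metrics,
                              columns = c("n_nodes", "n_edges", "mean_degree",
                                          "avg_path_length", "diameter",
                                          "density", "clustering",
                                          "modularity")) {
  tb <- if (is.data.frame(metrics)) metrics else dplyr::bind_rows(metrics)
  miss <- setdiff(columns, names(tb))
  if (length(miss)) stop("missing metric(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  m <- as.matrix(tb[columns])
  if (anyNA(m)) stop("missing metric values", call. = FALSE)
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0
  stats::dist(z)
}
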
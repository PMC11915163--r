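#' Detect network modules by greedy modularity maximisation
#'
#' Deterministic greedy agglomeration on the unweighted undirected simple
#' graph; the `seed` argument is accepted for interface uniformity (the
#' greedy algorithm involves no randomness).
#'
#' @param g An igraph network.
#' @param seed Unused; kept so every network stage takes a seed.
#' @return A list with `membership` (tibble `taxon_id`, `module`) and the
#'   partition's `modularity`.
#' @export
detect_modules <- function(g, seed = 1) {
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  gs <- igraph::simplify(g)
  if ("weight" %in% igraph::edge_attr_names(gs)) {
    gs <- igraph::delete_edge_attr(gs, "weight")   # signed weights: use topology only
  }
  cl <- igraph::cluster_fast_greedy(gs, weights = NULL)
  # cut the dendrogram ourselves: max modularity, ties to fewer modules
  counts <- seq_len(igraph::vcount(gs))
  best <- NULL
  best_q <- -Inf
  for (k in counts) {
    mk <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = k)),
                   error = function(e) NULL)
    if (is.null(mk)) next
    q <- igraph::modularity(gs, mk)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- mk
    }
  }
  memb <- stats::setNames(as.integer(best), igraph::V(gs)$name)
  list(membership = tibble::tibble(taxon_id = names(memb),
                                   module = as.integer(memb)),
       modularity = igraph::modularity(gs, memb))
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' `Zi = (k_is - mean_s) / sd_s`, where `k_is` is node i's degree inside
#' its own module s and the moments are over s's members (a module whose
#' members all have equal within-module degree gives Zi = 0);
#' `Pi = 1 - sum_m (k_im / k_i)^2` over modules m.
#'
#' @param g An igraph network with no isolated nodes.
#' @param partition Result of [detect_modules()] (or a tibble
#'   `taxon_id`, `module` covering all nodes).
#' @return A tibble `taxon_id`, `module`, `degree`, `zi`, `pi`.
#' @export
zi_pi <- function(g, partition) {
  memb <- if (is.data.frame(partition)) partition else partition$membership
  nodes <- igraph::V(g)$name
  if (any(igraph::degree(g) == 0)) {
    stop("network contains isolated nodes", call. = FALSE)
  }
  miss <- setdiff(nodes, memb$taxon_id)
  if (length(miss)) stop("partition does not cover: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  module <- memb$module[match(nodes, memb$taxon_id)]
  adj <- igraph::as_adjacency_matrix(igraph::simplify(g), sparse = FALSE)
  adj <- (adj > 0) + 0
  k <- rowSums(adj)
  # k_im: edges from node i into module m
  mods <- sort(unique(module))
  k_im <- vapply(mods, function(mm) rowSums(adj[, module == mm, drop = FALSE]),
                 numeric(length(nodes)))
  k_own <- k_im[cbind(seq_along(nodes), match(module, mods))]
  zi <- numeric(length(nodes))
  for (mm in mods) {
    idx <- which(module == mm)
    s <- stats::sd(k_own[idx])
    zi[idx] <- if (length(idx) < 2 || !is.finite(s) || s == 0) 0 else
      (k_own[idx] - mean(k_own[idx])) / s
  }
  pi <- 1 - rowSums((k_im / k)^2)
  tibble::tibble(taxon_id = nodes, module = module, degree = as.numeric(k),
                 zi = as.numeric(zi), pi = as.numeric(unname(pi)))
}

#' Classify nodes into topological roles
#'
#' Module hubs (`Zi >= 2.5, Pi < 0.62`), connectors (`Zi < 2.5,
#' Pi >= 0.62`), network hubs (`Zi >= 2.5, Pi >= 0.62`) — collectively
#' keystone nodes — and peripherals otherwise. Boundaries are inclusive on
#' the `>=` side.
#'
#' @param roles Tibble with `zi` and `pi` columns (from [zi_pi()]).
#' @param zi_threshold,pi_threshold Role thresholds.
#' @return `roles` with added `role` and logical `keystone` columns.
#' @export
classify_keystones <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- roles$zi >= zi_threshold
  hi_p <- roles$pi >= pi_threshold
  role <- dplyr::case_when(
    hi_z & hi_p ~ "network_hub",
    hi_z & !hi_p ~ "module_hub",
    !hi_z & hi_p ~ "connector",
    TRUE ~ "peripheral")
  dplyr::mutate(roles, role = role, keystone = role != "peripheral")
}

# Qualifying-correlation matrix: entries of rho that pass the network
# filter (or all nonzero entries when no p matrix / thresholds given).
qualifying_rho <- function(fit, r_threshold, p_threshold) {
  rho <- fit$rho
  keep <- abs(rho) > r_threshold
  if (!is.null(fit$p)) keep <- keep & (fit$p <= p_threshold)
  diag(keep) <- FALSE
  rho * keep
}

# Mean positive / negative qualifying correlation per taxon (0 if none).
cohesion_rbar <- function(q) {
  pos_n <- rowSums(q > 0)
  neg_n <- rowSums(q < 0)
  r_pos <- ifelse(pos_n > 0, rowSums(q * (q > 0)) / pmax(pos_n, 1), 0)
  r_neg <- ifelse(neg_n > 0, rowSums(q * (q < 0)) / pmax(neg_n, 1), 0)
  tibble::tibble(taxon_id = rownames(q), r_pos = r_pos, r_neg = r_neg)
}

#' Community cohesion from network-qualifying correlations
#'
#' For each taxon i, `r+_i` is the mean of its qualifying positive
#' correlations with other taxa (0 if none) and `r-_i` the analogue over
#' negative correlations; per sample the positive and negative cohesion
#' are the abundance-weighted sums `C+ = sum_i p_i r+_i` and
#' `C- = sum_i p_i r-_i`. By default qualifying correlations are the pairs
#' that pass the network edge filter; `method = "pearson_null"` instead
#' uses Pearson correlations corrected by a taxon-shuffle null
#' (the original cohesion formulation).
#'
#' @param rel An [abund_tbl()] with unit `relative_fraction`.
#' @param fit A `sparcc_result` covering the taxa of `rel` (ignored for
#'   `method = "pearson_null"`).
#' @param r_threshold,p_threshold Edge filter for qualifying correlations.
#' @param method `"network_edges"` (default) or `"pearson_null"`.
#' @param n_null Null iterations for `"pearson_null"`.
#' @param seed Seed for `"pearson_null"`.
#' @return A list of class `cohesion_result`: `samples` (tibble
#'   `sample_id`, `cohesion_pos`, `cohesion_neg`) and `r_bar` (per-taxon
#'   mean qualifying correlations).
#' @export
community_cohesion <- function(rel, fit = NULL, r_threshold = 0.6,
                               p_threshold = 0.05,
                     method = c("network_edges", "pearson_null"),
                     n_null = 200, seed = 1) {
  method <- match.arg(method)
  if (abund_unit(rel) != "relative_fraction") {
    stop("cohesion expects relative fractions; call to_relative() first",
         call. = FALSE)
  }
  m <- abund_matrix(rel)
  if (method == "network_edges") {
    stopifnot(inherits(fit, "sparcc_result"))
    common <- intersect(rownames(m), fit$taxon_ids)
    if (length(common) != nrow(m)) {
      stop("taxa of the table are not covered by the correlation result",
           call. = FALSE)
    }
    q <- qualifying_rho(fit, r_threshold, p_threshold)[rownames(m), rownames(m)]
  } else {
    obs <- stats::cor(t(m))
    set.seed(seed)
    null_mean <- matrix(0, nrow(m), nrow(m))
    for (b in seq_len(n_null)) {
      ms <- t(apply(m, 1L, sample))
      null_mean <- null_mean + stats::cor(t(ms))
    }
    q <- obs - null_mean / n_null
    diag(q) <- 0
    dimnames(q) <- list(rownames(m), rownames(m))
  }
  rb <- cohesion_rbar(q)
  samples <- tibble::tibble(
    sample_id = colnames(m),
    cohesion_pos = as.numeric(t(m) %*% rb$r_pos),
    cohesion_neg = as.numeric(t(m) %*% rb$r_neg))
  structure(list(samples = samples, r_bar = rb, method = method),
            class = "cohesion_result")
}

#' Cohesion response to random removal of a phylum's taxa
#'
#' For each removal fraction, random subsets of the phylum's taxa are
#' deleted, remaining relative abundances renormalised, cohesion recomputed
#' on the remaining taxa (mean qualifying correlations recomputed on the
#' remaining submatrix), and the mean over replicates and samples recorded;
#' the reported slope is the ordinary least-squares slope of mean cohesion
#' on removal fraction. Fraction 0 reproduces the unperturbed cohesion
#' exactly and fraction 1 equals the phylum-absent community.
#'
#' @param rel An [abund_tbl()] with unit `relative_fraction`.
#' @param fit A `sparcc_result` covering the taxa.
#' @param taxonomy Taxonomy tibble.
#' @param phylum Phylum whose taxa are removed.
#' @param fractions Removal fraction grid.
#' @param n_reps Random subsets per fraction.
#' @param seed Integer seed.
#' @inheritParams community_cohesion
#' @return A list of class `removal_trajectory`: `phylum`, `trajectory`
#'   (tibble `fraction`, `cohesion_pos`, `cohesion_neg`), `slope_pos`,
#'   `slope_neg`, `n_reps`, `seed`.
#' @export
removal_stability <- function(rel, fit, taxonomy, phylum,
                              fractions = seq(0, 1, by = 0.1), n_reps = 100,
                              seed = 1, r_threshold = 0.6, p_threshold = 0.05) {
  m <- abund_matrix(rel)
  q_full <- qualifying_rho(fit, r_threshold, p_threshold)[rownames(m), rownames(m)]
  phyla <- taxonomy$phylum[match(rownames(m), taxonomy$taxon_id)]
  members <- which(phyla == phylum)
  if (length(members) == 0L) {
    stop("phylum '", phylum, "' has no taxa in the table", call. = FALSE)
  }
  mean_cohesion <- function(keep_idx) {
    mk <- m[keep_idx, , drop = FALSE]
    cs <- colSums(mk)
    ok <- cs > 0
    if (!any(ok)) return(c(pos = NA_real_, neg = NA_real_))
    mk <- sweep(mk[, ok, drop = FALSE], 2L, cs[ok], "/")
    qk <- q_full[keep_idx, keep_idx, drop = FALSE]
    rb <- cohesion_rbar(qk)
    c(pos = mean(as.numeric(t(mk) %*% rb$r_pos)),
      neg = mean(as.numeric(t(mk) %*% rb$r_neg)))
  }
  all_idx <- seq_len(nrow(m))
  traj <- purrr::map_dfr(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    n_remove <- round(f * length(members))
    if (n_remove == 0L) {
      v <- mean_cohesion(all_idx)
      return(tibble::tibble(fraction = f, cohesion_pos = unname(v["pos"]),
                            cohesion_neg = unname(v["neg"])))
    }
    if (n_remove == length(members)) {
      v <- mean_cohesion(setdiff(all_idx, members))
      return(tibble::tibble(fraction = f, cohesion_pos = unname(v["pos"]),
                            cohesion_neg = unname(v["neg"])))
    }
    set.seed(substream_seed(seed, fi))
    reps <- vapply(seq_len(n_reps), function(r) {
      drop <- sample(members, n_remove)
      mean_cohesion(setdiff(all_idx, drop))
    }, numeric(2))
    tibble::tibble(fraction = f,
                   cohesion_pos = mean(reps["pos", ], na.rm = TRUE),
                   cohesion_neg = mean(reps["neg", ], na.rm = TRUE))
  })
  slope <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y[ok] ~ fractions[ok]))[2])
  }
  structure(list(phylum = phylum, trajectory = traj,
                 slope_pos = slope(traj$cohesion_pos),
                 slope_neg = slope(traj$cohesion_neg),
                 n_reps = n_reps, seed = seed),
            class = "removal_trajectory")
}

#' Classify taxa by the sign of their network association with a focal set
#'
#' Every non-focal node with at least one edge to a focal node is classed
#' by the sign of the sum of those edge weights (a sum of exactly zero is
#' classed positive — a probability-zero tie with continuous weights);
#' nodes without focal edges are `"none"`. Abundance-weighted class
#' fractions (including the focal share itself) are computed per period
#' from the absolute-abundance table.
#'
#' @param g An igraph network from [build_network()].
#' @param focal_taxa Character vector of focal node ids.
#' @param abundance An [abund_tbl()] (typically copies/mL) covering the
#'   community.
#' @param metadata Optional tibble `sample_id`, `period` for per-period
#'   fractions (otherwise one overall column).
#' @param taxonomy Optional taxonomy for a per-phylum breakdown.
#' @return A list of class `focal_association`: `nodes` (tibble
#'   `taxon_id`, `class`, `weight_sum`), `fractions` (per period:
#'   abundance fractions of positive/negative/none/focal, summing to 1),
#'   and optionally `by_phylum`.
#' @export
focal_association <- function(g, focal_taxa, abundance, metadata = NULL,
                              taxonomy = NULL) {
  nodes <- igraph::V(g)$name
  focal_in <- intersect(focal_taxa, nodes)
  if (length(intersect(focal_taxa, abundance$taxon_id)) == 0L) {
    stop("focal taxa absent from the abundance table", call. = FALSE)
  }
  el <- igraph::as_data_frame(g, what = "edges")
  weight_sum <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  touching <- el$from %in% focal_in | el$to %in% focal_in
  if (any(touching)) {
    elf <- el[touching, ]
    other <- ifelse(elf$from %in% focal_in, elf$to, elf$from)
    keep <- !(other %in% focal_taxa)
    ws <- tapply(elf$weight[keep], other[keep], sum)
    weight_sum[names(ws)] <- ws
  }
  node_class <- ifelse(is.na(weight_sum), "none",
                       ifelse(weight_sum >= 0, "positive", "negative"))
  node_tbl <- tibble::tibble(taxon_id = nodes, class = node_class,
                             weight_sum = as.numeric(weight_sum))
  m <- abund_matrix(abundance)
  cls <- rep("none", nrow(m))
  names(cls) <- rownames(m)
  cls[node_tbl$taxon_id] <- node_tbl$class
  cls[rownames(m) %in% focal_taxa] <- "focal"
  groups <- if (is.null(metadata)) {
    list(overall = colnames(m))
  } else {
    split(metadata$sample_id, metadata$period, drop = TRUE)
  }
  fractions <- purrr::imap_dfr(groups, function(samps, per) {
    tot <- rowSums(m[, intersect(samps, colnames(m)), drop = FALSE])
    s <- sum(tot)
    tibble::tibble(
      period = per,
      positive = sum(tot[cls == "positive"]) / s,
      negative = sum(tot[cls == "negative"]) / s,
      none = sum(tot[cls == "none"]) / s,
      focal = sum(tot[cls == "focal"]) / s)
  })
  out <- list(nodes = node_tbl, fractions = fractions)
  if (!is.null(taxonomy)) {
    out$by_phylum <- node_tbl |>
      dplyr::mutate(phylum = taxonomy$phylum[
        match(.data$taxon_id, taxonomy$taxon_id)]) |>
      dplyr::count(.data$phylum, .data$class)
  }
  structure(out, class = "focal_association")
}
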
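#' Configuration for the synthetic glacier-surface community generator
#'
#' The generator emulates the structure of a seasonal glacier-surface
#' survey: a prokaryote (16S) and a eukaryote (18S) marker-gene community
#' sampled over three periods (accumulation, melt, late melt) with ten
#' samples each; compositional counts produced by a Gaussian copula over
#' latent log-abundances followed by multinomial sequencing; per-sample
#' qPCR totals on the copies-per-mL scale; a focal phylum whose absolute
#' abundance rises sharply across periods; an optional dense positive
#' correlation block planted in a keystone phylum; and optional phylogenetic
#' environmental filtering of Brownian-evolving traits.
#'
#' @param n_taxa_prok,n_taxa_euk Numbers of prokaryote / eukaryote taxa
#'   (`n_taxa_euk = 0` disables the eukaryote community).
#' @param n_samples_per_period Samples per period.
#' @param periods Ordered period labels.
#' @param seed Master seed; all generator randomness derives from it.
#' @param correlation_spec Optional tibble (`taxon_i`, `taxon_j`, `rho`)
#'   of planted basis correlations between named taxa.
#' @param focal_phylum Focal phylum label (prokaryote side).
#' @param focal_multipliers Per-period multiplicative shifts of the focal
#'   taxa's mean abundance (length = number of periods).
#' @param keystone_phylum Phylum receiving a dense planted positive
#'   intra-correlation block (`NULL` disables planting).
#' @param keystone_rho Intra-block basis correlation.
#' @param keystone_cross Number of mixed-sign cross correlations per
#'   keystone taxon (at strength `keystone_cross_rho`, alternating sign).
#' @param keystone_cross_rho Magnitude of the planted cross correlations.
#' @param sigma_env Environmental-filtering width on the standardised trait
#'   scale; `Inf` disables filtering, small values filter strongly.
#' @param period_optima Per-period trait optima used when filtering is on.
#' @param sequencing_depth,sequencing_depth_euk Mean reads per sample for
#'   the two markers.
#' @param qpcr_total_means Per-period mean total (16S + 18S) gene copies
#'   per mL.
#' @param qpcr_prok_share Per-period fraction of the qPCR total carried by
#'   the 16S marker.
#' @param qpcr_log_sd Log-scale sd of the per-sample qPCR draws.
#' @param latent_sd Per-taxon sd of latent log-abundance.
#' @param baseline_sd Across-taxon sd of mean log-abundance.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa_prok = 120,
                       n_taxa_euk = 60,
                       n_samples_per_period = 10,
                       periods = c("accumulation", "melt", "late_melt"),
                       seed = 1,
                       correlation_spec = NULL,
                       focal_phylum = "Cyanobacteria",
                       focal_multipliers = c(0.02, 1, 3.2),
                       keystone_phylum = "Cyanobacteria",
                       keystone_rho = 0.7,
                       keystone_cross = 1,
                       keystone_cross_rho = 0.3,
                       sigma_env = Inf,
                       period_optima = NULL,
                       sequencing_depth = 5e4,
                       sequencing_depth_euk = 2e4,
                       qpcr_total_means = c(1.8e4, 2e8, 3.8e8),
                       qpcr_prok_share = c(0.2, 0.8, 0.92),
                       qpcr_log_sd = 0.3,
                       latent_sd = 1,
                       baseline_sd = 1.5) {
  n_p <- length(periods)
  if (length(focal_multipliers) != n_p) {
    stop("focal_multipliers must have one entry per period", call. = FALSE)
  }
  if (length(qpcr_total_means) == 1L) qpcr_total_means <- rep(qpcr_total_means, n_p)
  if (length(qpcr_prok_share) == 1L) qpcr_prok_share <- rep(qpcr_prok_share, n_p)
  stopifnot(length(qpcr_total_means) == n_p, length(qpcr_prok_share) == n_p)
  if (is.null(period_optima)) {
    period_optima <- if (n_p == 1L) 0 else seq(-1.2, 1.2, length.out = n_p)
  }
  stopifnot(n_taxa_prok >= 2, n_taxa_euk >= 0, n_samples_per_period >= 1,
            sigma_env > 0, sequencing_depth > 1)
  structure(list(
    n_taxa_prok = n_taxa_prok, n_taxa_euk = n_taxa_euk,
    n_samples_per_period = n_samples_per_period, periods = periods,
    seed = seed, correlation_spec = correlation_spec,
    focal_phylum = focal_phylum, focal_multipliers = focal_multipliers,
    keystone_phylum = keystone_phylum, keystone_rho = keystone_rho,
    keystone_cross = keystone_cross, keystone_cross_rho = keystone_cross_rho,
    sigma_env = sigma_env, period_optima = period_optima,
    sequencing_depth = sequencing_depth,
    sequencing_depth_euk = sequencing_depth_euk,
    qpcr_total_means = qpcr_total_means, qpcr_prok_share = qpcr_prok_share,
    qpcr_log_sd = qpcr_log_sd, latent_sd = latent_sd,
    baseline_sd = baseline_sd), class = "sim_config")
}

#' Simulate a rooted pure-birth phylogeny
#'
#' A Yule (pure-birth, exponential waiting time) tree conditioned on the
#' number of tips, with positive branch lengths.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param tip_labels Optional tip labels (length `n_taxa`).
#' @return An [ape::phylo] object.
#' @export
simulate_phylogeny <- function(n_taxa, seed = 1, tip_labels = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_taxa)
    tr$tip.label <- tip_labels
  }
  tr
}

# Deterministic phylum assignment for synthetic taxa.
synthetic_phyla_prok <- c("Cyanobacteria", "Proteobacteria", "Actinobacteriota",
                          "Bacteroidota", "Deinococcus-Thermus")
synthetic_phyla_euk <- c("SAR", "Ascomycota", "Phragmoplastophyta",
                         "Basidiomycota")

assign_phyla <- function(n, phyla) {
  if (n == 0L) return(character())
  sort(rep(phyla, length.out = n))
}

# Build the planted basis correlation matrix over all taxa.
build_basis_correlation <- function(cfg, ids, phylum) {
  d <- length(ids)
  R <- diag(d)
  dimnames(R) <- list(ids, ids)
  if (!is.null(cfg$keystone_phylum) && cfg$keystone_rho > 0) {
    ks <- which(phylum == cfg$keystone_phylum)
    if (length(ks) >= 2) {
      R[ks, ks] <- cfg$keystone_rho
      diag(R)[] <- 1
      if (cfg$keystone_cross > 0 && cfg$keystone_cross_rho > 0) {
        others <- setdiff(seq_len(d), ks)
        sgn <- 1
        oi <- 1L
        for (i in ks) {
          for (m in seq_len(cfg$keystone_cross)) {
            if (oi > length(others)) break
            j <- others[oi]
            R[i, j] <- R[j, i] <- sgn * cfg$keystone_cross_rho
            sgn <- -sgn
            oi <- oi + 1L
          }
        }
      }
    }
  }
  if (!is.null(cfg$correlation_spec) && nrow(cfg$correlation_spec)) {
    cs <- cfg$correlation_spec
    for (k in seq_len(nrow(cs))) {
      i <- match(as.character(cs$taxon_i[k]), ids)
      j <- match(as.character(cs$taxon_j[k]), ids)
      if (is.na(i) || is.na(j)) {
        stop("correlation_spec names unknown taxa", call. = FALSE)
      }
      R[i, j] <- R[j, i] <- cs$rho[k]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    stop("planted correlation structure is not positive definite; ",
         "shrink the planted correlations toward zero", call. = FALSE)
  }
  R
}

#' Simulate prokaryote and eukaryote communities with known ground truth
#'
#' Latent log-abundances are drawn from a multivariate normal whose
#' correlation matrix embeds the planted structure (Gaussian copula);
#' optional environmental filtering subtracts
#' `(trait - optimum_period)^2 / (2 sigma_env^2)` from the latent mean,
#' with traits evolving under Brownian motion on the supplied trees; counts
#' are multinomial draws of the per-sample softmax composition at the
#' configured sequencing depth; qPCR totals are log-normal around the
#' per-period means.
#'
#' @param cfg A [sim_config()].
#' @param tree_prok,tree_euk Optional [ape::phylo] trees whose tips cover
#'   the generated taxa; simulated internally when omitted.
#' @return A list with elements `prok`, `euk` ([abund_tbl()]s of reads),
#'   `qpcr`, `metadata`, `taxonomy`, `tree_prok`, `tree_euk`, and `truth`
#'   (basis correlation matrix, traits, keystone set, per-period focal
#'   absolute abundance).
#' @export
simulate_communities <- function(cfg, tree_prok = NULL, tree_euk = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ids_p <- sprintf("p_zotu_%03d", seq_len(cfg$n_taxa_prok))
  ids_e <- if (cfg$n_taxa_euk > 0) sprintf("e_zotu_%03d", seq_len(cfg$n_taxa_euk)) else character()
  ids <- c(ids_p, ids_e)
  d <- length(ids)
  phylum <- c(assign_phyla(cfg$n_taxa_prok, synthetic_phyla_prok),
              assign_phyla(cfg$n_taxa_euk, synthetic_phyla_euk))
  domain <- c(rep("Bacteria", cfg$n_taxa_prok), rep("Eukaryota", cfg$n_taxa_euk))
  taxonomy <- tibble::tibble(taxon_id = ids, domain = domain, phylum = phylum,
                             class = "unclassified", order = "unclassified",
                             family = "unclassified", genus = "unclassified")

  if (is.null(tree_prok)) {
    tree_prok <- simulate_phylogeny(cfg$n_taxa_prok,
                                    seed = substream_seed(cfg$seed, 11),
                                    tip_labels = ids_p)
  }
  if (is.null(tree_euk) && cfg$n_taxa_euk >= 2) {
    tree_euk <- simulate_phylogeny(cfg$n_taxa_euk,
                                   seed = substream_seed(cfg$seed, 12),
                                   tip_labels = ids_e)
  }
  missing_tips <- setdiff(ids_p, tree_prok$tip.label)
  if (length(missing_tips)) stop("tree_prok does not cover all prokaryote taxa",
                                 call. = FALSE)

  R <- build_basis_correlation(cfg, ids, phylum)

  set.seed(substream_seed(cfg$seed, 1))
  baseline <- stats::rnorm(d, 0, cfg$baseline_sd)

  # Brownian traits on each tree, standardised; filtering acts on these.
  trait <- stats::setNames(rep(0, d), ids)
  if (is.finite(cfg$sigma_env)) {
    bm_trait <- function(tree) {
      V <- ape::vcv(tree)
      x <- MASS::mvrnorm(1, mu = rep(0, nrow(V)), Sigma = V)
      stats::setNames(as.numeric(scale(x)), rownames(V))
    }
    set.seed(substream_seed(cfg$seed, 2))
    tp <- bm_trait(tree_prok)
    trait[names(tp)] <- tp
    if (!is.null(tree_euk)) {
      te <- bm_trait(tree_euk)
      trait[names(te)] <- te
    }
  }

  n_per <- cfg$n_samples_per_period
  n_p <- length(cfg$periods)
  n_samples <- n_per * n_p
  period_of <- rep(seq_len(n_p), each = n_per)
  samples <- sprintf("%s_s%02d", cfg$periods[period_of],
                     rep(seq_len(n_per), times = n_p))
  metadata <- tibble::tibble(sample_id = samples,
                             period = factor(cfg$periods[period_of],
                                             levels = cfg$periods))

  Sigma <- (cfg$latent_sd^2) * R
  set.seed(substream_seed(cfg$seed, 3))
  latent <- MASS::mvrnorm(n_samples, mu = rep(0, d), Sigma = Sigma)
  latent <- t(latent)                      # taxa x samples
  dimnames(latent) <- list(ids, samples)

  focal <- phylum == cfg$focal_phylum
  for (p in seq_len(n_p)) {
    cols <- which(period_of == p)
    mu <- baseline
    mu[focal] <- mu[focal] + log(cfg$focal_multipliers[p])
    if (is.finite(cfg$sigma_env)) {
      mu <- mu - (trait - cfg$period_optima[p])^2 / (2 * cfg$sigma_env^2)
    }
    latent[, cols] <- latent[, cols] + mu
  }

  draw_counts <- function(rows, depth) {
    comp <- softmax_cols(latent[rows, , drop = FALSE])
    depths <- stats::rpois(n_samples, depth)
    m <- vapply(seq_len(n_samples),
                function(s) stats::rmultinom(1, depths[s], comp[, s])[, 1],
                numeric(length(rows)))
    dimnames(m) <- list(ids[rows], samples)
    m
  }
  set.seed(substream_seed(cfg$seed, 4))
  counts_p <- draw_counts(seq_len(cfg$n_taxa_prok), cfg$sequencing_depth)
  counts_e <- NULL
  if (cfg$n_taxa_euk > 0) {
    set.seed(substream_seed(cfg$seed, 5))
    counts_e <- draw_counts(cfg$n_taxa_prok + seq_len(cfg$n_taxa_euk),
                            cfg$sequencing_depth_euk)
  }

  set.seed(substream_seed(cfg$seed, 6))
  mean16 <- cfg$qpcr_total_means * cfg$qpcr_prok_share
  mean18 <- cfg$qpcr_total_means * (1 - cfg$qpcr_prok_share)
  copies_16s <- exp(stats::rnorm(n_samples, log(mean16[period_of]), cfg$qpcr_log_sd))
  copies_18s <- if (cfg$n_taxa_euk > 0) {
    exp(stats::rnorm(n_samples, log(pmax(mean18[period_of], 1e-12)), cfg$qpcr_log_sd))
  } else rep(0, n_samples)
  qpcr <- tibble::tibble(sample_id = samples, copies_16s = copies_16s,
                         copies_18s = copies_18s)

  prok <- abund_from_matrix(counts_p, unit = "reads")
  euk <- if (!is.null(counts_e)) abund_from_matrix(counts_e, unit = "reads") else NULL

  frac_focal <- colSums(counts_p[focal[seq_len(cfg$n_taxa_prok)], , drop = FALSE]) /
    pmax(colSums(counts_p), 1)
  focal_abs <- frac_focal * copies_16s
  truth <- list(
    basis_correlation = R,
    trait = trait,
    keystone_taxa = ids[phylum == (cfg$keystone_phylum %||% "")],
    focal_taxa = ids[focal],
    focal_abs_per_sample = stats::setNames(focal_abs, samples),
    focal_abs_per_period = tapply(focal_abs, cfg$periods[period_of], mean)
  )
  list(prok = prok, euk = euk, qpcr = qpcr, metadata = metadata,
       taxonomy = taxonomy, tree_prok = tree_prok, tree_euk = tree_euk,
       truth = truth)
}

#' Placeholder list of 39 nitrogen-cycle enzyme identifiers
#'
#' EC-style labels for nitrogen-metabolism reactions (nitrogen fixation,
#' nitrification, denitrification, assimilation, urea and amide turnover).
#' This synthetic placeholder list names the schema of the function table;
#' it is not a curated pathway annotation, and real analyses should supply
#' their own enzyme table.
#'
#' @return Character vector of length 39.
#' @export
nitrogen_enzymes <- function() {
  c("EC:1.18.6.1", "EC:1.19.6.1", "EC:1.7.99.4", "EC:1.7.5.1", "EC:1.7.1.1",
    "EC:1.7.1.2", "EC:1.7.1.3", "EC:1.7.7.1", "EC:1.7.7.2", "EC:1.7.2.1",
    "EC:1.7.2.4", "EC:1.7.2.5", "EC:1.7.2.6", "EC:1.7.1.15", "EC:1.7.3.4",
    "EC:1.14.99.39", "EC:1.14.13.25", "EC:1.7.1.4", "EC:1.7.1.14",
    "EC:6.3.1.2", "EC:1.4.1.13", "EC:1.4.1.14", "EC:1.4.1.2", "EC:1.4.1.3",
    "EC:1.4.1.4", "EC:1.4.7.1", "EC:3.5.1.5", "EC:3.5.1.4", "EC:3.5.5.1",
    "EC:3.5.1.49", "EC:6.3.4.6", "EC:2.7.2.2", "EC:3.5.1.54", "EC:4.2.1.104",
    "EC:3.5.5.7", "EC:2.1.4.1", "EC:2.6.1.1", "EC:2.6.1.2", "EC:1.4.3.16")
}

#' Slope linking focal abundance to enzyme abundances for a target R-squared
#'
#' For the generator's additive model, the population coefficient of
#' determination of the multifunctionality index regressed on the focal
#' z-score is `beta^2 / (beta^2 + sigma^2 / n_enzymes)`; this inverts that
#' relation.
#'
#' @param target_r2 Desired population R-squared in (0, 1).
#' @param sigma Per-enzyme noise sd.
#' @param n_enzymes Number of enzymes averaged.
#' @return The slope `beta`.
#' @export
beta_for_r2 <- function(target_r2, sigma = 1, n_enzymes = 39) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  sigma * sqrt(target_r2 / ((1 - target_r2) * n_enzymes))
}

#' Simulate an enzyme-by-sample function table
#'
#' Each enzyme's abundance is an enzyme-specific baseline plus
#' `beta * z(focal_abundance)` plus Gaussian noise; the table is shifted to
#' be non-negative.
#'
#' @param focal_abundance Named numeric vector of per-sample focal
#'   abundance (names = sample ids).
#' @param n_enzymes Number of enzymes (default 39 nitrogen-metabolism
#'   reactions).
#' @param beta Linear effect of the standardised focal abundance.
#' @param sigma Noise sd.
#' @param seed Integer seed.
#' @param enzyme_ids Optional enzyme labels (defaults to
#'   [nitrogen_enzymes()] when `n_enzymes` is 39).
#' @return A tibble `enzyme_id` plus one column per sample.
#' @export
simulate_function_table <- function(focal_abundance, n_enzymes = 39,
                                    beta = 0.5, sigma = 1, seed = 1,
                                    enzyme_ids = NULL) {
  stopifnot(beta >= 0, sigma >= 0)
  if (is.null(enzyme_ids)) {
    enzyme_ids <- if (n_enzymes == 39) nitrogen_enzymes() else
      sprintf("enzyme_%02d", seq_len(n_enzymes))
  }
  stopifnot(length(enzyme_ids) == n_enzymes)
  n_s <- length(focal_abundance)
  z <- if (stats::sd(focal_abundance) > 0) {
    as.numeric(scale(focal_abundance))
  } else rep(0, n_s)
  set.seed(seed)
  alpha <- stats::rnorm(n_enzymes, 5, 1)
  vals <- outer(alpha, rep(1, n_s)) + beta * outer(rep(1, n_enzymes), z) +
    matrix(stats::rnorm(n_enzymes * n_s, 0, sigma), n_enzymes, n_s)
  if (min(vals) < 0) vals <- vals - min(vals)
  colnames(vals) <- names(focal_abundance)
  dplyr::bind_cols(tibble::tibble(enzyme_id = enzyme_ids),
                   tibble::as_tibble(vals, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
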
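#' Configuration for the full seasonal community analysis
#'
#' Bundles input locations (or a simulation configuration), the network
#' and keystone thresholds, permutation/bootstrap counts and the focal
#' phylum into one object consumed by [run_pipeline()].
#'
#' @param simulate Logical; generate inputs with [simulate_communities()].
#' @param sim A [sim_config()] when `simulate = TRUE`.
#' @param paths Named list of input files when `simulate = FALSE`:
#'   `counts_16s`, `counts_18s`, `taxonomy`, `tree_prok`, `tree_euk`,
#'   `qpcr`, `metadata`, and optionally `function_table` (TSV / newick).
#' @param focal_phylum Focal phylum name.
#' @param r_threshold,p_threshold Network edge filter.
#' @param zi_threshold,pi_threshold Keystone role thresholds.
#' @param n_boot Bootstrap datasets for correlation p-values.
#' @param n_perm Permutations for PERMANOVA / Procrustes.
#' @param n_null Null randomisations for NRI/NTI/betaNTI.
#' @param n_removal_reps Replicates per removal fraction.
#' @param removal_fractions Removal fraction grid.
#' @param n_dominant Number of dominant phyla screened.
#' @param scope `"merged"` (16S+18S absolute table, default) or
#'   `"per_marker"` for diversity and ordination.
#' @param function_beta,function_sigma Effect and noise of the simulated
#'   function table (`function_beta = NULL` targets a population
#'   R-squared of 0.5 via [beta_for_r2()]).
#' @param seed Master seed.
#' @param output_dir Optional directory for the JSON report and TSVs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            paths = NULL,
                            focal_phylum = "Cyanobacteria",
                            r_threshold = 0.6, p_threshold = 0.05,
                            zi_threshold = 2.5, pi_threshold = 0.62,
                            n_boot = 999, n_perm = 999, n_null = 999,
                            n_removal_reps = 100,
                            removal_fractions = seq(0, 1, by = 0.1),
                            n_dominant = 6, scope = c("merged", "per_marker"),
                            function_beta = NULL, function_sigma = 1,
                            seed = 1, output_dir = NULL) {
  scope <- match.arg(scope)
  stopifnot(r_threshold > 0, r_threshold < 1, p_threshold > 0, p_threshold <= 1,
            n_boot >= 1, n_perm >= 1, n_null >= 1)
  if (is.null(function_beta)) {
    function_beta <- beta_for_r2(0.5, sigma = function_sigma, n_enzymes = 39)
  }
  reduced <- n_boot < 999 || n_perm < 999 || n_null < 999
  structure(list(simulate = simulate, sim = sim, paths = paths,
                 focal_phylum = focal_phylum,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 zi_threshold = zi_threshold, pi_threshold = pi_threshold,
                 n_boot = n_boot, n_perm = n_perm, n_null = n_null,
                 n_removal_reps = n_removal_reps,
                 removal_fractions = removal_fractions,
                 n_dominant = n_dominant, scope = scope,
                 function_beta = function_beta,
                 function_sigma = function_sigma,
                 seed = seed, output_dir = output_dir,
                 reduced_precision = reduced),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

load_inputs <- function(config) {
  if (config$simulate) {
    sim <- config$sim
    sim$seed <- substream_seed(config$seed, 100)
    simulate_communities(sim)
  } else {
    p <- config$paths
    need <- c("counts_16s", "counts_18s", "taxonomy", "tree_prok",
              "tree_euk", "qpcr", "metadata")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    list(prok = read_count_table(p$counts_16s),
         euk = read_count_table(p$counts_18s),
         taxonomy = read_taxonomy(p$taxonomy),
         tree_prok = ape::read.tree(p$tree_prok),
         tree_euk = ape::read.tree(p$tree_euk),
         qpcr = read_qpcr(p$qpcr),
         metadata = read_sample_metadata(p$metadata),
         truth = NULL,
         function_table = if (!is.null(p$function_table))
           read_function_table(p$function_table) else NULL)
  }
}

#' Procrustes screen of dominant phyla against the rest of the community
#'
#' For each phylum, the phylum-only subcommunity ordination is compared to
#' the ordination of the community with that phylum removed; a small
#' Procrustes `m2` indicates that the phylum's compositional changes track
#' the rest of the community. p-values are BH-adjusted across phyla.
#'
#' @param x An [abund_tbl()].
#' @param taxonomy Taxonomy tibble.
#' @param phyla Phyla to screen (each needs >= 2 taxa; others are skipped
#'   with a warning).
#' @param n_perm Procrustes permutations.
#' @param seed Integer seed.
#' @param n_axes Ordination axes compared (default 2).
#' @return A tibble `phylum`, `m2`, `p_value`, `p_adjusted`, `n_taxa`.
#' @export
procrustes_screen <- function(x, taxonomy, phyla, n_perm = 999, seed = 1,
                              n_axes = 2) {
  ph_of <- taxonomy$phylum[match(x$taxon_id, taxonomy$taxon_id)]
  out <- list()
  for (k in seq_along(phyla)) {
    ph <- phyla[k]
    members <- which(ph_of == ph)
    if (length(members) < 2L) {
      warning("phylum '", ph, "' has < 2 taxa; skipped")
      next
    }
    sub <- abund_tbl(x[members, , drop = FALSE], unit = abund_unit(x))
    rest <- abund_tbl(x[-members, , drop = FALSE], unit = abund_unit(x))
    pa <- pca_ordination(sub)
    pb <- pca_ordination(rest)
    take <- function(o) {
      m <- as.matrix(o$scores[-1])
      rownames(m) <- o$scores$sample_id
      m[, seq_len(min(n_axes, ncol(m))), drop = FALSE]
    }
    pr <- procrustes_concordance(take(pa), take(pb), n_perm = n_perm,
                                 seed = substream_seed(seed, k))
    out[[length(out) + 1L]] <- tibble::tibble(
      phylum = ph, m2 = pr$m2, p_value = pr$p_value,
      n_taxa = length(members))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res$p_adjusted <- bh_adjust(res$p_value)
  res
}

# Pearson regression summary used by the cross-period analyses.
lm_summary <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(slope = NA_real_, r = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  fit <- summary(stats::lm(y ~ x))
  ct <- stats::cor.test(x, y)
  tibble::tibble(slope = fit$coefficients[2, 1],
                 r = unname(ct$estimate), r_squared = fit$r.squared,
                 p_value = fit$coefficients[2, 4], n = length(x))
}

#' Run the full seasonal community analysis
#'
#' Executes the stages in dependency order: input loading (or simulation),
#' organelle filtering, qPCR absolute-abundance integration, alpha/beta
#' diversity and PERMANOVA, per-period SparCC networks with bootstrap
#' significance and topology, module/keystone/cohesion/removal analyses,
#' focal-taxon association, phylogenetic community structure and betaNTI,
#' per-phylum turnover and Venn partition, Procrustes screening of
#' dominant phyla, cross-period regressions, and the nitrogen-metabolism
#' multifunctionality association.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- stage("input", load_inputs(config))
  periods <- levels(inp$metadata$period)

  dat <- stage("organelle_filter", {
    list(prok = filter_organelles(inp$prok, inp$taxonomy),
         euk = if (!is.null(inp$euk)) filter_organelles(inp$euk, inp$taxonomy))
  })

  absolute <- stage("qpcr_integration", {
    if (!is.null(dat$euk)) integrate_qpcr(dat$prok, dat$euk, inp$qpcr)
    else {
      m <- abund_matrix(to_relative(dat$prok))
      q <- inp$qpcr[match(colnames(m), inp$qpcr$sample_id), ]
      abund_from_matrix(sweep(m, 2L, q$copies_16s, "*"), unit = "copies_per_ml")
    }
  })
  merged_counts <- stage("merge_counts", {
    if (!is.null(dat$euk)) {
      abund_from_matrix(rbind(abund_matrix(dat$prok), abund_matrix(dat$euk)),
                        unit = "reads")
    } else dat$prok
  })

  diversity <- stage("diversity", {
    div_one <- function(tbl) {
      a <- alpha_diversity(tbl)
      list(alpha = a,
           tests = alpha_diversity_tests(a, inp$metadata))
    }
    if (config$scope == "merged") {
      div_one(absolute)
    } else {
      list(prok = div_one(dat$prok), euk = if (!is.null(dat$euk)) div_one(dat$euk))
    }
  })

  ordination <- stage("ordination", {
    tbl <- if (config$scope == "merged") absolute else dat$prok
    pc <- pca_ordination(tbl)
    d <- community_distance(tbl, "bray_curtis")
    groups <- inp$metadata$period[match(attr(d, "Labels") %||% labels(d),
                                        inp$metadata$sample_id)]
    list(pca = pc,
         permanova = permanova(d, groups, n_perm = config$n_perm,
                               seed = substream_seed(config$seed, 21)))
  })

  focal_ids <- inp$taxonomy$taxon_id[inp$taxonomy$phylum == config$focal_phylum]

  networks <- stage("networks", {
    purrr::imap(stats::setNames(periods, periods), function(per, nm) {
      samps <- inp$metadata$sample_id[inp$metadata$period == per]
      sub <- abund_tbl(merged_counts[, c("taxon_id", samps)], unit = "reads")
      keep <- rowSums(abund_matrix(sub)) > 0
      sub <- abund_tbl(sub[keep, , drop = FALSE], unit = "reads")
      pseed <- substream_seed(config$seed, 30 + match(per, periods))
      fit <- sparcc(sub, seed = pseed)
      fit <- sparcc_bootstrap(sub, fit, n_boot = config$n_boot,
                              seed = substream_seed(pseed, 1))
      g <- build_network(fit, r_threshold = config$r_threshold,
                         p_threshold = config$p_threshold,
                         taxonomy = inp$taxonomy)
      list(period = per, counts = sub, fit = fit, graph = g)
    })
  })

  topology <- stage("topology", {
    purrr::map_dfr(networks, function(nw) {
      if (igraph::vcount(nw$graph) == 0L) {
        return(tibble::tibble(period = nw$period, n_nodes = 0, n_edges = 0))
      }
      dplyr::bind_cols(tibble::tibble(period = nw$period),
                       network_topology(nw$graph))
    })
  })

  keystones <- stage("keystones", {
    purrr::map_dfr(networks, function(nw) {
      if (igraph::vcount(nw$graph) == 0L) return(tibble::tibble())
      part <- detect_modules(nw$graph)
      roles <- classify_keystones(zi_pi(nw$graph, part),
                                  zi_threshold = config$zi_threshold,
                                  pi_threshold = config$pi_threshold)
      dplyr::mutate(roles, period = nw$period, .before = 1)
    })
  })

  dominant <- stage("dominant_phyla", {
    ph <- aggregate_by_rank(absolute, inp$taxonomy, "phylum")
    tot <- sort(rowSums(abund_matrix(ph)), decreasing = TRUE)
    head(names(tot), config$n_dominant)
  })

  cohesion_res <- stage("cohesion", {
    purrr::map(networks, function(nw) {
      rel <- to_relative(nw$counts)
      community_cohesion(rel, nw$fit, r_threshold = config$r_threshold,
               p_threshold = config$p_threshold)$samples |>
        dplyr::mutate(period = nw$period, .before = 1)
    }) |> dplyr::bind_rows()
  })

  removal <- stage("removal_stability", {
    purrr::map_dfr(networks, function(nw) {
      rel <- to_relative(nw$counts)
      ph_here <- intersect(
        dominant,
        inp$taxonomy$phylum[match(rel$taxon_id, inp$taxonomy$taxon_id)])
      purrr::map_dfr(ph_here, function(ph) {
        tr <- removal_stability(rel, nw$fit, inp$taxonomy, ph,
                                fractions = config$removal_fractions,
                                n_reps = config$n_removal_reps,
                                seed = substream_seed(config$seed,
                                                      50 + match(ph, dominant)),
                                r_threshold = config$r_threshold,
                                p_threshold = config$p_threshold)
        tibble::tibble(period = nw$period, phylum = ph,
                       slope_pos = tr$slope_pos, slope_neg = tr$slope_neg)
      })
    })
  })

  focal <- stage("focal_association", {
    purrr::map(networks, function(nw) {
      if (igraph::vcount(nw$graph) == 0L) return(NULL)
      samps <- inp$metadata[inp$metadata$period == nw$period, ]
      fa <- focal_association(nw$graph, focal_ids, absolute,
                              metadata = samps, taxonomy = inp$taxonomy)
      dplyr::mutate(fa$fractions, period = nw$period)
    }) |> purrr::compact() |> dplyr::bind_rows()
  })

  phylo <- stage("phylo_metrics", {
    one_marker <- function(tbl, tree, offset) {
      if (is.null(tbl) || is.null(tree)) return(NULL)
      nonfocal <- setdiff(tbl$taxon_id, focal_ids)
      sub <- abund_tbl(tbl[tbl$taxon_id %in% nonfocal, , drop = FALSE],
                       unit = abund_unit(tbl))
      phylo_community_metrics(sub, tree, n_null = config$n_null,
                              seed = substream_seed(config$seed, offset))
    }
    list(prok = one_marker(dat$prok, inp$tree_prok, 61),
         euk = one_marker(dat$euk, inp$tree_euk, 62))
  })

  focal_abs <- stage("focal_abundance", {
    m <- abund_matrix(absolute)
    colSums(m[intersect(focal_ids, rownames(m)), , drop = FALSE])
  })

  assembly <- stage("assembly", {
    focal_tbl <- absolute[absolute$taxon_id %in% focal_ids, , drop = FALSE]
    if (nrow(focal_tbl) < 1) return(NULL)
    focal_d <- community_distance(
      abund_tbl(focal_tbl, unit = "copies_per_ml"), "sorensen")
    one <- function(tbl, tree, offset) {
      if (is.null(tbl) || is.null(tree)) return(NULL)
      nonfocal <- tbl[!tbl$taxon_id %in% focal_ids, , drop = FALSE]
      bnti <- beta_nti_matrix(abund_tbl(nonfocal, unit = abund_unit(tbl)),
                              tree, n_null = config$n_null,
                              seed = substream_seed(config$seed, offset))
      dm <- as.matrix(focal_d)
      bnti$focal_distance <- dm[cbind(bnti$sample_a, bnti$sample_b)]
      list(pairs = bnti,
           regression = lm_summary(bnti$focal_distance, bnti$beta_nti))
    }
    list(prok = one(dat$prok, inp$tree_prok, 71),
         euk = one(dat$euk, inp$tree_euk, 72))
  })

  turnover_res <- stage("turnover", {
    per_tbl <- lapply(periods, function(per) {
      samps <- inp$metadata$sample_id[inp$metadata$period == per]
      abund_tbl(merged_counts[, c("taxon_id", samps)], unit = "reads")
    })
    names(per_tbl) <- periods
    pairs <- utils::combn(seq_along(periods), 2)
    tv <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      turnover(per_tbl[[i]], per_tbl[[j]], inp$taxonomy, "phylum") |>
        dplyr::mutate(period_a = periods[i], period_b = periods[j],
                      .before = 1)
    })
    pres <- lapply(per_tbl, function(tb)
      tb$taxon_id[rowSums(abund_matrix(tb)) > 0])
    list(turnover = tv, venn = venn_partition(pres))
  })

  procrustes_res <- stage("procrustes_screen", {
    procrustes_screen(absolute, inp$taxonomy, dominant,
                      n_perm = config$n_perm,
                      seed = substream_seed(config$seed, 81))
  })

  cross_period <- stage("cross_period", {
    if (nrow(topology) < 3 || any(topology$n_nodes == 0)) return(NULL)
    td <- as.matrix(topology_distance(topology))
    dimnames(td) <- list(topology$period, topology$period)
    focal_pooled <- purrr::map(periods, function(per) {
      samps <- inp$metadata$sample_id[inp$metadata$period == per]
      m <- abund_matrix(merged_counts)[, samps, drop = FALSE]
      rowSums(m[intersect(focal_ids, rownames(m)), , drop = FALSE] > 0) > 0
    })
    sor <- function(a, b) {
      if (sum(a) + sum(b) == 0) return(NA_real_)
      1 - 2 * sum(a & b) / (sum(a) + sum(b))
    }
    pairs <- utils::combn(seq_along(periods), 2)
    tb <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      tibble::tibble(period_a = periods[i], period_b = periods[j],
                     focal_sorensen = sor(focal_pooled[[i]], focal_pooled[[j]]),
                     topology_distance = td[periods[i], periods[j]])
    })
    list(pairs = tb,
         regression = lm_summary(tb$focal_sorensen, tb$topology_distance))
  })

  multifun <- stage("multifunctionality", {
    fn <- if (config$simulate || is.null(inp$function_table)) {
      simulate_function_table(focal_abs, n_enzymes = 39,
                              beta = config$function_beta,
                              sigma = config$function_sigma,
                              seed = substream_seed(config$seed, 91))
    } else inp$function_table
    mf <- multifunctionality_index(fn)
    list(index = mf$index,
         regression = associate_multifunctionality(mf, focal_abs))
  })

  report <- structure(list(
    settings = list(
      seed = config$seed, focal_phylum = config$focal_phylum,
      r_threshold = config$r_threshold, p_threshold = config$p_threshold,
      zi_threshold = config$zi_threshold, pi_threshold = config$pi_threshold,
      n_boot = config$n_boot, n_perm = config$n_perm, n_null = config$n_null,
      scope = config$scope, simulate = config$simulate,
      reduced_precision = config$reduced_precision),
    periods = periods,
    diversity = diversity,
    ordination = list(var_explained = ordination$pca$var_explained,
                      scores = ordination$pca$scores,
                      permanova = ordination$permanova),
    topology = topology,
    keystones = keystones,
    cohesion = cohesion_res,
    removal_slopes = removal,
    focal_association = focal,
    phylo_metrics = phylo,
    assembly = list(prok = assembly$prok["regression"],
                    euk = assembly$euk["regression"]),
    assembly_pairs = list(prok = assembly$prok$pairs, euk = assembly$euk$pairs),
    turnover = turnover_res$turnover,
    venn = turnover_res$venn,
    procrustes = procrustes_res,
    cross_period = cross_period,
    multifunctionality = multifun
  ), class = "analysis_report")

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' Serialise an analysis report
#'
#' Writes `report.json` (lossless, 15 significant digits) plus TSVs of the
#' main tables into `dir`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  tsv <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x)) {
      utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  tsv(report$topology, "topology.tsv")
  tsv(report$keystones, "keystones.tsv")
  tsv(report$cohesion, "cohesion.tsv")
  tsv(report$removal_slopes, "removal_slopes.tsv")
  tsv(report$turnover, "turnover.tsv")
  invisible(dir)
}

#' JSON text of an analysis report
#' @param report An `analysis_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = I(15), na = "null", null = "null",
                                dataframe = "columns"))
}
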
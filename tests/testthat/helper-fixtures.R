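# Small fixtures built in code; all randomness is seeded.

tiny_counts <- function() {
  abund_tbl(data.frame(taxon_id = c("z1", "z2", "z3"),
                       s1 = c(3, 1, 0), s2 = c(2, 2, 6)), unit = "reads")
}

tiny_taxonomy <- function(ids = c("z1", "z2", "z3"),
                          phylum = c("Cyanobacteria", "Proteobacteria",
                                     "Proteobacteria")[seq_along(ids)]) {
  tibble::tibble(taxon_id = ids, domain = "Bacteria", phylum = phylum,
                 class = "unclassified", order = "unclassified",
                 family = "unclassified", genus = "unclassified")
}

# 4-tip tree with printed branch lengths used in the PD hand checks.
fixture_tree <- function() {
  ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):6);")
}

star_tree <- function(n = 4) {
  tips <- paste0("t", seq_len(n))
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# Symmetric correlation matrix + optional p matrix -> sparcc_result.
corr_fixture <- function(entries, ids, p_entries = NULL) {
  d <- length(ids)
  rho <- diag(d); dimnames(rho) <- list(ids, ids)
  for (e in entries) { rho[e[[1]], e[[2]]] <- rho[e[[2]], e[[1]]] <- e[[3]] }
  p <- NULL
  if (!is.null(p_entries)) {
    p <- matrix(1, d, d, dimnames = list(ids, ids))
    for (e in p_entries) { p[e[[1]], e[[2]]] <- p[e[[2]], e[[1]]] <- e[[3]] }
  }
  correlation_result(rho, p)
}

# Null-structured community for SparCC calibration checks.
null_sim <- function(n_taxa = 30, n_samples = 100, seed = 1, depth = 5e4) {
  cfg <- sim_config(n_taxa_prok = n_taxa, n_taxa_euk = 0,
                    n_samples_per_period = n_samples, periods = "melt",
                    focal_multipliers = 1, qpcr_total_means = 2e8,
                    qpcr_prok_share = 1, keystone_phylum = NULL,
                    sequencing_depth = depth, seed = seed)
  simulate_communities(cfg)
}
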
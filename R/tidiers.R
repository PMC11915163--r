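#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a SparCC correlation result into an edge-candidate tibble
#'
#' @param x A `sparcc_result`.
#' @param ... Unused.
#' @return A tibble `taxon_a`, `taxon_b`, `rho` (and `p` when available),
#'   one row per unordered pair.
#' @export
tidy.sparcc_result <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(taxon_a = rownames(x$rho)[idx[, 1]],
                        taxon_b = colnames(x$rho)[idx[, 2]],
                        rho = x$rho[idx])
  if (!is.null(x$p)) out$p <- x$p[idx]
  out
}

#' @rdname tidy.sparcc_result
#' @export
glance.sparcc_result <- function(x, ...) {
  tibble::tibble(n_taxa = length(x$taxon_ids),
                 n_bootstrap = x$n_bootstrap %||% NA_integer_,
                 iterations = x$settings$iterations %||% NA_integer_,
                 max_abs_rho = max(abs(x$rho[upper.tri(x$rho)])))
}

#' Tidy a Procrustes concordance result
#'
#' @param x A `procrustes_concordance`.
#' @param ... Unused.
#' @return Per-sample residuals as a tibble.
#' @export
tidy.procrustes_concordance <- function(x, ...) {
  tibble::tibble(sample_id = names(x$residuals),
                 residual = as.numeric(x$residuals))
}

#' @rdname tidy.procrustes_concordance
#' @export
glance.procrustes_concordance <- function(x, ...) {
  tibble::tibble(m2 = x$m2, correlation = x$correlation,
                 p_value = x$p_value, n_perm = x$n_perm)
}

#' Tidy a removal trajectory
#'
#' @param x A `removal_trajectory`.
#' @param ... Unused.
#' @return The per-fraction mean cohesion tibble with the phylum attached.
#' @export
tidy.removal_trajectory <- function(x, ...) {
  dplyr::mutate(x$trajectory, phylum = x$phylum, .before = 1)
}

#' @rdname tidy.removal_trajectory
#' @export
glance.removal_trajectory <- function(x, ...) {
  tibble::tibble(phylum = x$phylum, slope_pos = x$slope_pos,
                 slope_neg = x$slope_neg, n_reps = x$n_reps)
}

#' Tidy a cohesion result
#'
#' @param x A `cohesion_result`.
#' @param ... Unused.
#' @return The per-sample cohesion tibble.
#' @export
tidy.cohesion_result <- function(x, ...) x$samples
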
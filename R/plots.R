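#' Ordination scatter plot
#'
#' @param pca A `pca_ordination`.
#' @param metadata Optional tibble `sample_id`, `period` for colouring.
#' @param axes Which axes to draw.
#' @return A ggplot.
#' @export
plot_ordination <- function(pca, metadata = NULL, axes = c(1, 2)) {
  sc <- pca$scores
  ax <- paste0("PC", axes)
  dat <- sc[, c("sample_id", ax)]
  names(dat) <- c("sample_id", "x", "y")
  if (!is.null(metadata)) {
    dat <- dplyr::left_join(dat, metadata, by = "sample_id")
  }
  lab <- function(i) {
    ve <- pca$var_explained[axes[i]]
    if (is.na(ve)) ax[i] else sprintf("%s (%.1f%%)", ax[i], 100 * ve)
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$period), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Zi-Pi role plot
#'
#' Scatter of within-module degree versus among-module connectivity with
#' the keystone threshold lines.
#'
#' @param roles Tibble from [classify_keystones()].
#' @param zi_threshold,pi_threshold Thresholds to draw.
#' @return A ggplot.
#' @export
plot_zipi <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = 2) +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module degree (Zi)") +
    ggplot2::theme_minimal()
}

#' Cohesion removal trajectories
#'
#' @param trajectories A list of `removal_trajectory` objects (or one).
#' @param which `"pos"` or `"neg"` cohesion.
#' @return A ggplot.
#' @export
plot_removal <- function(trajectories, which = c("pos", "neg")) {
  which <- match.arg(which)
  if (inherits(trajectories, "removal_trajectory")) {
    trajectories <- list(trajectories)
  }
  dat <- purrr::map_dfr(trajectories, function(tr) {
    dplyr::mutate(tr$trajectory, phylum = tr$phylum)
  })
  ycol <- paste0("cohesion_", which)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data[[ycol]],
                                    colour = .data$phylum)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Fraction of phylum removed",
                  y = sprintf("Mean %s cohesion",
                              if (which == "pos") "positive" else "negative")) +
    ggplot2::theme_minimal()
}

#' Multifunctionality association plot
#'
#' @param mf A `multifunctionality` result.
#' @param focal_abundance Named per-sample focal abundance.
#' @return A ggplot with the OLS fit line.
#' @export
plot_multifunctionality <- function(mf, focal_abundance) {
  idx <- mf$index
  dat <- dplyr::mutate(idx, abundance = as.numeric(
    focal_abundance[idx$sample_id]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$abundance,
                                    y = .data$multifunctionality)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Focal-phylum abundance",
                  y = "Multifunctionality index") +
    ggplot2::theme_minimal()
}
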
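#' Drop focal-phylum taxa before functional prediction
#'
#' The community table handed to gene-content prediction excludes the
#' focal phylum so that the multifunctionality of the *other* organisms is
#' not confounded by the focal taxa's own gene content.
#'
#' @param x An [abund_tbl()].
#' @param taxonomy Taxonomy tibble.
#' @param focal_phylum Phylum to exclude.
#' @return The filtered `abund_tbl`.
#' @export
exclude_focal <- function(x, taxonomy, focal_phylum) {
  ph <- taxonomy$phylum[match(x$taxon_id, taxonomy$taxon_id)]
  keep <- is.na(ph) | ph != focal_phylum
  if (!any(keep)) stop("excluding '", focal_phylum,
                       "' leaves an empty table", call. = FALSE)
  abund_tbl(x[keep, , drop = FALSE], unit = abund_unit(x))
}

#' Multifunctionality index by z-score averaging
#'
#' Each enzyme's per-sample abundances are standardised
#' (`z = (x - mean) / sd`, sample sd with denominator n - 1); the
#' per-sample index is the mean z-score over enzymes, so indices are
#' centred on 0 across samples. Zero-variance enzymes are dropped with a
#' warning.
#'
#' @param fn A function table tibble (`enzyme_id` + sample columns).
#' @return A list of class `multifunctionality`: `index` (tibble
#'   `sample_id`, `multifunctionality`), `z` (enzyme x sample z-score
#'   matrix), `n_enzymes`.
#' @export
multifunctionality_index <- function(fn) {
  m <- as.matrix(fn[setdiff(names(fn), "enzyme_id")])
  rownames(m) <- fn$enzyme_id
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance enzyme(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(m) == 0L) stop("no enzymes with nonzero variance", call. = FALSE)
  z <- (m - rowMeans(m)) / sds
  idx <- colMeans(z)
  structure(list(index = tibble::tibble(sample_id = colnames(m),
                                        multifunctionality = as.numeric(idx)),
                 z = z, n_enzymes = nrow(m)),
            class = "multifunctionality")
}

#' Regression of multifunctionality on focal abundance
#'
#' Ordinary least squares of the per-sample index on per-sample focal
#' abundance, with the slope's two-sided p-value and the fit's R-squared.
#'
#' @param mf A `multifunctionality` result (or its `index` tibble).
#' @param focal_abundance Named per-sample numeric vector (names matching
#'   sample ids) or a tibble `sample_id`, `abundance`.
#' @return A one-row tibble `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
associate_multifunctionality <- function(mf, focal_abundance) {
  idx <- if (inherits(mf, "multifunctionality")) mf$index else
    tibble::as_tibble(mf)
  fa <- if (is.data.frame(focal_abundance)) {
    stats::setNames(focal_abundance$abundance, focal_abundance$sample_id)
  } else focal_abundance
  stopifnot(!is.null(names(fa)))
  common <- intersect(idx$sample_id, names(fa))
  if (length(common) < 3L) stop("need at least 3 matched samples", call. = FALSE)
  y <- idx$multifunctionality[match(common, idx$sample_id)]
  x <- as.numeric(fa[common])
  if (stats::sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(common))
}
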
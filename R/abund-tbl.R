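#' Abundance tables
#'
#' The package's universal community object is a wide tibble: a character
#' column `taxon_id` followed by one numeric column per sample. A `unit`
#' attribute records whether the values are sequencing `reads`, per-sample
#' `relative_fraction`s, or qPCR-scaled `copies_per_ml`.
#'
#' @param x A data frame with a `taxon_id` column and numeric sample columns.
#' @param unit One of `"reads"`, `"relative_fraction"`, `"copies_per_ml"`.
#' @return A validated `abund_tbl` (a tibble subclass).
#' @examples
#' abund_tbl(data.frame(taxon_id = c("z1", "z2"), s1 = c(3, 1)), unit = "reads")
#' @export
abund_tbl <- function(x, unit = c("reads", "relative_fraction", "copies_per_ml")) {
  unit <- match.arg(unit)
  x <- tibble::as_tibble(x)
  if (!"taxon_id" %in% names(x)) {
    stop("abundance table must have a 'taxon_id' column", call. = FALSE)
  }
  x <- dplyr::relocate(x, "taxon_id")
  if (ncol(x) < 2L) stop("abundance table has no sample columns", call. = FALSE)
  if (nrow(x) < 1L) stop("abundance table has no taxa", call. = FALSE)
  x$taxon_id <- as.character(x$taxon_id)
  if (anyDuplicated(x$taxon_id)) {
    stop("duplicate taxon ids: ",
         paste(unique(x$taxon_id[duplicated(x$taxon_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) stop("duplicate sample ids", call. = FALSE)
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
  if (anyNA(vals)) stop("abundance values contain NA", call. = FALSE)
  if (any(vals < 0)) stop("abundance values must be non-negative", call. = FALSE)
  if (unit == "relative_fraction") {
    cs <- colSums(vals)
    bad <- abs(cs - 1) > 1e-9
    if (any(bad)) {
      stop("relative_fraction columns must sum to 1: ",
           paste(colnames(vals)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(x, unit = unit, class = c("abund_tbl", class(tibble::tibble())))
}

#' @rdname abund_tbl
#' @export
abund_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) "reads" else u
}

#' @rdname abund_tbl
#' @export
sample_ids <- function(x) setdiff(names(x), "taxon_id")

#' @rdname abund_tbl
#' @export
taxon_ids <- function(x) x$taxon_id

#' Convert between abundance tibbles and taxa-by-sample matrices
#'
#' @param x An `abund_tbl`.
#' @param m A numeric matrix with taxon rownames and sample colnames.
#' @inheritParams abund_tbl
#' @return `abund_matrix()` a taxa x samples matrix; `abund_from_matrix()`
#'   an `abund_tbl`.
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "taxon_id")])
  rownames(m) <- x$taxon_id
  m
}

#' @rdname abund_matrix
#' @export
abund_from_matrix <- function(m, unit = "reads") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  abund_tbl(dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                             tibble::as_tibble(m, .name_repair = "minimal")),
            unit = unit)
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat("# Abundance table (", abund_unit(x), "): ", nrow(x), " taxa x ",
      ncol(x) - 1L, " samples\n", sep = "")
  NextMethod()
}
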
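#' Derive a substream seed from a master seed
#'
#' All randomness in the package flows from one user seed; independent
#' stages use substreams `seed + 104729 * k (mod 2^31 - 1)` so that the same
#' configuration always reproduces the same output regardless of the order
#' in which stages are run.
#'
#' @param seed Master integer seed.
#' @param k Substream index (non-negative integer).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

# Dirichlet draw per row: counts is samples x taxa; returns fractions with
# the same shape. Unit prior (alpha = counts + 1).
rdirichlet_rows <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
              nrow = nrow(counts))
  g / rowSums(g)
}

# Row-wise minima of a matrix (vectorised over columns).
row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

softmax_cols <- function(x) {
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(x)
  sweep(e, 2L, colSums(e), "/")
}

bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
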
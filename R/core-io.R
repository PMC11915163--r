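#' Read a taxon-by-sample count table
#'
#' Accepts the two interchange formats used for denoised amplicon (ZOTU)
#' tables: a UTF-8 tab-separated file whose first column holds taxon ids and
#' whose header row holds sample ids, or a BIOM JSON file.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return An [abund_tbl()] with unit `"reads"`, row and column order as in
#'   the file.
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(x) < 2L) stop("parse error in ", path, ": need a taxon id column plus >= 1 sample column",
                           call. = FALSE)
    names(x)[1] <- "taxon_id"
    for (j in seq(2L, ncol(x))) {
      if (!is.numeric(x[[j]])) {
        stop("parse error in ", path, ": column '", names(x)[j], "' is not numeric",
             call. = FALSE)
      }
    }
    abund_tbl(x, unit = "reads")
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    abund_from_matrix(m, unit = "reads")
  }
}

#' Write a count table as TSV
#'
#' @param x An [abund_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank names of a taxonomy table
#' @keywords internal
tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Two layouts are accepted: a TSV with columns `taxon_id`, `domain`,
#' `phylum`, `class`, `order`, `family`, `genus`; or a two-column TSV
#' (`taxon_id`, `lineage`) with a QIIME-style lineage string
#' (`d__...; p__...; ...`, separators `;`), missing ranks filled with
#' `"unclassified"`.
#'
#' @param path File path.
#' @return A tibble with `taxon_id` plus the six rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(x)[1] <- "taxon_id"
  if (ncol(x) == 2L) {
    lin <- strsplit(as.character(x[[2]]), ";", fixed = TRUE)
    lin <- lapply(lin, function(v) {
      v <- sub("^\\s*[a-z]__", "", trimws(v))
      v <- v[v != ""]
      length(v) <- 6L
      v[is.na(v)] <- "unclassified"
      v
    })
    m <- do.call(rbind, lin)
    colnames(m) <- tax_ranks()
    x <- dplyr::bind_cols(tibble::tibble(taxon_id = as.character(x$taxon_id)),
                          tibble::as_tibble(m))
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(tax_ranks(), names(x))
  for (r in missing) x[[r]] <- "unclassified"
  x$taxon_id <- as.character(x$taxon_id)
  if (anyDuplicated(x$taxon_id)) stop("duplicate taxon ids in taxonomy", call. = FALSE)
  dplyr::select(x, "taxon_id", dplyr::all_of(tax_ranks()))
}

#' Read a per-sample qPCR table
#'
#' Expects columns `sample_id`, `copies_16s`, `copies_18s` (16S and 18S rRNA
#' gene copies per millilitre).
#'
#' @param path File path.
#' @return A tibble `sample_id`, `copies_16s`, `copies_18s`.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  names(x) <- tolower(names(x))
  stopifnot(all(c("sample_id", "copies_16s", "copies_18s") %in% names(x)))
  if (any(x$copies_16s < 0) || any(x$copies_18s < 0)) {
    stop("qPCR copies must be non-negative", call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Read per-sample metadata (sampling period labels)
#'
#' @param path File path to a TSV with columns `sample_id` and `period`.
#' @param periods Optional ordered period labels; defaults to the order of
#'   first appearance.
#' @return A tibble `sample_id`, `period` (factor with ordered levels).
#' @export
read_sample_metadata <- function(path, periods = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sample_id", "period") %in% names(x)))
  x$sample_id <- as.character(x$sample_id)
  if (is.null(periods)) periods <- unique(x$period)
  x$period <- factor(x$period, levels = periods)
  x
}

#' Read an enzyme-by-sample function table
#'
#' @param path TSV whose first column is the enzyme id and whose remaining
#'   columns are per-sample predicted abundances.
#' @return A tibble with column `enzyme_id` plus sample columns.
#' @export
read_function_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                           stringsAsFactors = FALSE))
  names(x)[1] <- "enzyme_id"
  x$enzyme_id <- as.character(x$enzyme_id)
  if (anyDuplicated(x$enzyme_id)) stop("duplicate enzyme ids", call. = FALSE)
  x
}

#' Remove chloroplast and mitochondrial taxa
#'
#' Amplicon tables routinely contain organelle-derived 16S sequences;
#' lineages containing "chloroplast" or "mitochondria" (case-insensitive
#' substring, any rank) are dropped.
#'
#' @param x An [abund_tbl()].
#' @param taxonomy Taxonomy tibble covering all taxa in `x`.
#' @return The filtered `abund_tbl` (unit preserved).
#' @export
filter_organelles <- function(x, taxonomy) {
  miss <- setdiff(x$taxon_id, taxonomy$taxon_id)
  if (length(miss)) {
    stop("taxa missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tx <- taxonomy[match(x$taxon_id, taxonomy$taxon_id), tax_ranks()]
  lineage <- tolower(apply(as.matrix(tx), 1L, paste, collapse = ";"))
  organelle <- grepl("chloroplast", lineage, fixed = TRUE) |
    grepl("mitochondria", lineage, fixed = TRUE)
  out <- x[!organelle, , drop = FALSE]
  if (nrow(out) == 0L) stop("all taxa were organelle-annotated", call. = FALSE)
  abund_tbl(out, unit = abund_unit(x))
}

#' Convert counts to per-sample relative fractions
#'
#' @param x An [abund_tbl()].
#' @return An `abund_tbl` with unit `"relative_fraction"`; each sample
#'   column sums to 1.
#' @export
to_relative <- function(x) {
  m <- abund_matrix(x)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("all-zero sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", "),
         call. = FALSE)
  }
  abund_from_matrix(sweep(m, 2L, cs, "/"), unit = "relative_fraction")
}

#' Scale two marker-gene communities to absolute abundance with qPCR totals
#'
#' Per-marker relative fractions are multiplied by that marker's measured
#' gene copies per millilitre (16S for the prokaryote table, 18S for the
#' eukaryote table) and the two scaled tables are concatenated. The
#' per-sample total of the result equals `copies_16s + copies_18s`.
#'
#' @param prok,euk [abund_tbl()]s sharing sample ids, with disjoint taxa.
#' @param qpcr Tibble from [read_qpcr()].
#' @return An `abund_tbl` with unit `"copies_per_ml"`.
#' @export
integrate_qpcr <- function(prok, euk, qpcr) {
  samples <- sample_ids(prok)
  if (!setequal(samples, sample_ids(euk))) {
    stop("prokaryote and eukaryote tables must share sample ids", call. = FALSE)
  }
  overlap <- intersect(prok$taxon_id, euk$taxon_id)
  if (length(overlap)) {
    stop("overlapping taxon ids: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(samples, qpcr$sample_id)
  if (length(miss)) {
    stop("samples absent from qPCR table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  q <- qpcr[match(samples, qpcr$sample_id), ]
  scale_one <- function(tbl, copies) {
    m <- abund_matrix(to_relative(tbl))[, samples, drop = FALSE]
    sweep(m, 2L, copies, "*")
  }
  m <- rbind(scale_one(prok, q$copies_16s), scale_one(euk, q$copies_18s))
  abund_from_matrix(m, unit = "copies_per_ml")
}

#' Aggregate a count table at a taxonomic rank
#'
#' Rows are summed within identical rank labels; `"unclassified"` labels are
#' kept distinct per parent lineage (so unclassified members of different
#' higher-rank groups are not pooled).
#'
#' @param x An [abund_tbl()].
#' @param taxonomy Taxonomy tibble covering all taxa in `x`.
#' @param rank One of `domain, phylum, class, order, family, genus`.
#' @return An `abund_tbl` whose `taxon_id` column holds rank labels.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, tax_ranks())
  miss <- setdiff(x$taxon_id, taxonomy$taxon_id)
  if (length(miss)) {
    stop("taxa missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tx <- taxonomy[match(x$taxon_id, taxonomy$taxon_id), ]
  parents <- tax_ranks()[seq_len(match(rank, tax_ranks()) - 1L)]
  label <- as.character(tx[[rank]])
  uncl <- label == "unclassified"
  if (any(uncl) && length(parents)) {
    parent_str <- apply(as.matrix(tx[parents]), 1L, paste, collapse = ";")
    label[uncl] <- paste0("unclassified (", parent_str[uncl], ")")
  }
  m <- abund_matrix(x)
  agg <- rowsum(m, group = label, reorder = FALSE)
  abund_from_matrix(as.matrix(agg), unit = abund_unit(x))
}
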
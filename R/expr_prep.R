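# Expression preparation: expressed-gene filtering on counts-per-million,
# log-CPM normalization, and partitioning genes into tranches of similar
# median expression for multi-task training.

#' Construct a count matrix
#'
#' @param counts non-negative integer matrix, genes x samples, with gene
#'   identifiers as rownames and sample identifiers as colnames.
#' @return a `count_matrix` (the matrix with a `library_sizes` attribute).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("count matrix needs gene rownames and sample colnames")
  }
  if (any(counts < 0)) stop_input("counts must be non-negative")
  structure(counts, library_sizes = colSums(counts), class = c("count_matrix", "matrix"))
}

cpm_of <- function(counts, library_sizes = NULL) {
  lib <- library_sizes %||% colSums(counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    nm <- colnames(counts)[zero] %||% as.character(zero)
    stop_input("all-zero library for sample(s): %s", paste(nm, collapse = ", "))
  }
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Filter expressed genes
#'
#' Keeps genes whose counts-per-million reach `cpm_min` in at least
#' `frac_samples` of the samples (the usual expressed-gene rule applied to
#' bulk RNA counts, which retains on the order of 18,000 genes on real tumor
#' cohorts at the defaults). Input gene order is preserved.
#'
#' @param counts genes x samples count matrix (matrix or [count_matrix()]).
#' @param cpm_min minimum counts-per-million (default 1).
#' @param frac_samples minimum fraction of samples at or above `cpm_min`
#'   (default 0.2).
#' @param library_sizes optional per-sample library sizes; defaults to the
#'   column sums of `counts`.
#' @return character vector of kept gene identifiers.
#' @export
filter_expressed_genes <- function(counts, cpm_min = 1, frac_samples = 0.2,
                                   library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_input("need at least 2 samples to filter genes")
  if (cpm_min <= 0) return(rownames(counts))
  cpm <- cpm_of(counts, library_sizes)
  keep <- rowMeans(cpm >= cpm_min) >= frac_samples
  rownames(counts)[keep]
}

#' Normalize expression to log2(1 + CPM)
#'
#' Per-sample scaling to counts-per-million followed by `log2(1 + CPM)`. This
#' removes library-size differences between samples and compresses the
#' dynamic range of counts; the recipe applied is recorded in the
#' `normalization_tag` attribute for provenance.
#'
#' @param counts genes x samples count matrix (typically already filtered
#'   with [filter_expressed_genes()]).
#' @param library_sizes optional per-sample library sizes; defaults to the
#'   column sums of `counts`.
#' @return numeric matrix of the same shape, class `expression_matrix`.
#' @export
normalize_expression <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  expr <- log2(1 + cpm_of(counts, library_sizes))
  structure(expr, normalization_tag = "log2(1+CPM)",
            class = c("expression_matrix", "matrix"))
}

#' Partition genes into tranches of similar median expression
#'
#' Genes are sorted by per-gene median expression (descending, ties broken
#' lexicographically by gene identifier so the partition is deterministic)
#' and chunked into consecutive blocks of `tranche_size`; the last block may
#' be smaller. Each tranche is later fitted by one multi-task regressor, so
#' genes trained together share a similar expression scale.
#'
#' @param expr genes x samples matrix of normalized expression.
#' @param tranche_size genes per tranche (4096 for whole-genome runs).
#' @return list of `gene_tranche` objects, each with `tranche_index`
#'   (0-based), `gene_ids` and `median_range`.
#' @export
make_tranches <- function(expr, tranche_size = 4096L) {
  stopifnot(tranche_size >= 1L)
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L) return(list())
  med <- apply(expr, 1L, median)
  ord <- order(-med, rownames(expr))
  genes <- rownames(expr)[ord]
  med <- med[ord]
  starts <- seq(1L, length(genes), by = tranche_size)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:min(starts[k] + tranche_size - 1L, length(genes))
    structure(list(tranche_index = k - 1L,
                   gene_ids = genes[idx],
                   median_range = range(med[idx])),
              class = "gene_tranche")
  })
}

#' @export
print.gene_tranche <- function(x, ...) {
  cat(sprintf("<gene_tranche> #%d: %d genes, median range [%.3g, %.3g]\n",
              x$tranche_index, length(x$gene_ids),
              x$median_range[1], x$median_range[2]))
  invisible(x)
}

#' Tranche assignment table
#'
#' @param tranches list from [make_tranches()].
#' @param expr the expression matrix the tranches were built from.
#' @return data.frame with `gene_id`, `tranche_index`, `median`.
#' @export
tranche_table <- function(tranches, expr) {
  med <- apply(as.matrix(expr), 1L, median)
  do.call(rbind, lapply(tranches, function(tr) {
    data.frame(gene_id = tr$gene_ids, tranche_index = tr$tranche_index,
               median = med[tr$gene_ids], stringsAsFactors = FALSE)
  }))
}
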
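#' Cell-by-gene count matrix with aligned metadata
#'
#' Lightweight container for an integer cell x gene count matrix together with
#' row-aligned cell metadata and column-aligned gene metadata. Cells are rows,
#' genes are columns. The constructor validates alignment and recomputes the
#' per-cell summary columns `n_umi` (total counts) and `n_genes_detected`
#' (genes with at least one count).
#'
#' @param counts cell x gene matrix of nonnegative integers (dense or
#'   `Matrix` sparse); dimnames give cell ids (rows) and gene ids (columns).
#' @param cell_meta data.frame with one row per cell. Expected columns:
#'   `cell_id`, `donor`, `replicate`, `time_h`, `glucose_arm` ("low"/"high"),
#'   `contamination_frac`, `mito_frac`. Extra columns are kept.
#' @param gene_meta data.frame with one row per gene. Expected columns:
#'   `gene_id`, `symbol`, `chromosome`, `is_mito`, `is_ribo`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(counts, cell_meta, gene_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(counts) == nrow(cell_meta), ncol(counts) == nrow(gene_meta))
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(rownames(counts))) rownames(counts) <- cell_meta$cell_id
  if (is.null(colnames(counts))) colnames(counts) <- gene_meta$gene_id
  cell_meta$n_umi <- as.numeric(Matrix::rowSums(counts))
  cell_meta$n_genes_detected <- as.numeric(Matrix::rowSums(counts > 0))
  rownames(cell_meta) <- cell_meta$cell_id
  rownames(gene_meta) <- gene_meta$gene_id
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  donors: %s | time points (h): %s\n",
              paste(unique(x$cell_meta$donor), collapse = ", "),
              paste(sort(unique(x$cell_meta$time_h)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset a count_matrix by cell and/or gene index, keeping metadata aligned.
subset_cm <- function(x, cells = NULL, genes = NULL) {
  cts <- x$counts
  cm <- x$cell_meta
  gm <- x$gene_meta
  if (!is.null(cells)) {
    cts <- cts[cells, , drop = FALSE]
    cm <- cm[cells, , drop = FALSE]
  }
  if (!is.null(genes)) {
    cts <- cts[, genes, drop = FALSE]
    gm <- gm[genes, , drop = FALSE]
  }
  count_matrix(cts, cm, gm)
}

#' ln(CP10K+1) expression matrix
#'
#' Container pairing a normalized expression matrix (cells x genes,
#' ln(CP10K+1)) with the metadata of the filtered [count_matrix] it was
#' derived from.
#'
#' @param values cell x gene numeric matrix of ln(CP10K+1) values.
#' @param cell_meta,gene_meta metadata data.frames aligned to `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_meta, gene_meta) {
  stopifnot(nrow(values) == nrow(cell_meta), ncol(values) == nrow(gene_meta))
  structure(list(values = values, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
#' @method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, ln(CP10K+1)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
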
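#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket coordinate integer, the
#' 10x orientation), `features.tsv` (gene_id, symbol, type), `barcodes.tsv`,
#' and `cell_metadata.tsv` with the per-cell metadata columns. A paired read
#' with [read_tenx()] round-trips losslessly.
#'
#' @param matrix a [count_matrix].
#' @param directory output directory; created if missing.
#' @param truth optional ground-truth list from [simulate_dataset()]; written
#'   as `truth_genes.tsv` / `truth_cells.tsv`.
#' @return Invisibly, the directory path.
#' @export
write_tenx <- function(matrix, directory, truth = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (any(matrix$counts@x != round(matrix$counts@x)))
    stop("counts must be integers")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  mm <- Matrix::t(matrix$counts)  # genes x cells, the 10x orientation
  Matrix::writeMM(mm, file.path(directory, "matrix.mtx"))
  feat <- data.frame(gene_id = matrix$gene_meta$gene_id,
                     symbol = matrix$gene_meta$symbol,
                     type = "Gene Expression")
  write.table(feat, file.path(directory, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(matrix$cell_meta$cell_id, file.path(directory, "barcodes.tsv"))
  write.table(matrix$cell_meta, file.path(directory, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(matrix$gene_meta, file.path(directory, "gene_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    write.table(truth$genes, file.path(directory, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth$cells, file.path(directory, "truth_cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(directory)
}

#' Read a 10x-style MatrixMarket directory
#'
#' @param directory directory written by [write_tenx()] (or any 10x-dialect
#'   trio `matrix.mtx` + `features.tsv` + `barcodes.tsv`; cell metadata is
#'   read from `cell_metadata.tsv` when present).
#' @return A [count_matrix].
#' @export
read_tenx <- function(directory) {
  mm <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  counts <- Matrix::t(mm)  # back to cells x genes
  feat <- read.delim(file.path(directory, "features.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  gm_path <- file.path(directory, "gene_metadata.tsv")
  if (file.exists(gm_path)) {
    gene_meta <- read.delim(gm_path, stringsAsFactors = FALSE)
  } else {
    gene_meta <- data.frame(gene_id = feat[[1]], symbol = feat[[2]],
                            chromosome = NA_character_,
                            is_mito = grepl("^MT-", feat[[2]]),
                            is_ribo = grepl("^RP[SL]", feat[[2]]),
                            stringsAsFactors = FALSE)
  }
  cm_path <- file.path(directory, "cell_metadata.tsv")
  if (file.exists(cm_path)) {
    cell_meta <- read.delim(cm_path, stringsAsFactors = FALSE)
  } else {
    cell_meta <- data.frame(cell_id = barcodes, stringsAsFactors = FALSE)
  }
  rownames(counts) <- barcodes
  colnames(counts) <- feat[[1]]
  count_matrix(counts, cell_meta, gene_meta)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard GMT format (set name, description, then tab-separated
#' gene ids, one set per line).
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique gene ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  if (any(lengths(sets) == 0)) stop("GMT contains an empty gene set")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
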
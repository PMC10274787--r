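#' Apply cell and gene quality-control filters
#'
#' Filters, in fixed order: (1) cells with ambient contamination strictly
#' above `contamination_max`; (2) cells with mitochondrial fraction strictly
#' above `mito_max`; (3) UMI/complexity outlier cells; (4) genes expressed
#' (>= 1 count) in at most `gene_min_cells` of the surviving cells; (5)
#' mitochondrial and ribosomal genes. Gene prevalence is computed on
#' surviving cells because cells are filtered first.
#'
#' @param matrix a [count_matrix].
#' @param contamination_max cells with `contamination_frac` > this are
#'   removed (default 0.10; a cell at exactly 0.10 is retained).
#' @param mito_max cells with `mito_frac` > this are removed (default 0.50).
#' @param gene_min_cells genes expressed in <= this many cells are removed.
#' @param outlier_method `"robust_z"` (default; median/MAD z on log n_umi and
#'   log n_genes_detected, removing |z| > `outlier_z`) or
#'   `"isolation_forest"` (randomized isolation trees on the same two
#'   features, seeded, removing the `outlier_forest_frac` most isolable
#'   cells) or `"none"`.
#' @param outlier_z robust-z cutoff.
#' @param outlier_forest_frac contamination fraction for the isolation
#'   forest variant.
#' @param seed seed for the isolation forest.
#' @return A filtered [count_matrix] with a `qc_report` attribute: a
#'   data.frame of removal counts per rule.
#' @export
apply_qc_filters <- function(matrix, contamination_max = 0.10,
                             mito_max = 0.50, gene_min_cells = 5,
                             outlier_method = c("robust_z",
                                                "isolation_forest", "none"),
                             outlier_z = 4, outlier_forest_frac = 0.01,
                             seed = 1) {
  stopifnot(inherits(matrix, "count_matrix"),
            contamination_max >= 0, contamination_max <= 1,
            mito_max >= 0, mito_max <= 1)
  outlier_method <- match.arg(outlier_method)
  cm <- matrix$cell_meta
  n0 <- nrow(cm)
  fail_contam <- cm$contamination_frac > contamination_max
  fail_mito <- cm$mito_frac > mito_max
  keep1 <- !(fail_contam | fail_mito)
  if (!any(keep1)) stop("all cells removed by QC filters")
  feats <- cbind(log(cm$n_umi + 1), log(cm$n_genes_detected + 1))
  out <- rep(FALSE, n0)
  if (outlier_method == "robust_z") {
    z <- apply(feats, 2, function(v) {
      m <- median(v[keep1]); s <- mad(v[keep1])
      if (s == 0) rep(0, length(v)) else (v - m) / s
    })
    out <- apply(abs(z) > outlier_z, 1, any)
  } else if (outlier_method == "isolation_forest") {
    score <- isolation_scores(feats[keep1, , drop = FALSE], seed = seed)
    cut <- quantile(score, 1 - outlier_forest_frac)
    out[keep1] <- score > cut
  }
  keep_cells <- keep1 & !out
  if (!any(keep_cells)) stop("all cells removed by QC filters")
  sub <- subset_cm(matrix, cells = which(keep_cells))
  prevalence <- as.numeric(Matrix::colSums(sub$counts > 0))
  low_prev <- prevalence <= gene_min_cells
  mito_ribo <- sub$gene_meta$is_mito | sub$gene_meta$is_ribo
  keep_genes <- !(low_prev | mito_ribo)
  res <- subset_cm(sub, genes = which(keep_genes))
  report <- data.frame(
    rule = c("contamination", "mito_fraction", "umi_outlier",
             "gene_low_prevalence", "gene_mito_ribo"),
    removed = c(sum(fail_contam), sum(fail_mito & !fail_contam),
                sum(out & keep1), sum(low_prev),
                sum(mito_ribo & !low_prev)))
  attr(res, "qc_report") <- report
  res
}

# Minimal isolation forest: average path length over randomized trees;
# higher score = more isolable. Deterministic given seed.
isolation_scores <- function(x, n_trees = 100, sample_size = 256, seed = 1) {
  n <- nrow(x)
  sample_size <- min(sample_size, n)
  with_seed(seed, {
    depths <- matrix(0, n, n_trees)
    for (t in seq_len(n_trees)) {
      idx <- sample(n, sample_size)
      depths[, t] <- iso_tree_depth(x, x[idx, , drop = FALSE], 0,
                                    ceiling(log2(sample_size)))
    }
    avg <- rowMeans(depths)
    c_n <- 2 * (log(sample_size - 1) + 0.5772156649) -
      2 * (sample_size - 1) / sample_size
    2^(-avg / c_n)
  })
}

iso_tree_depth <- function(xq, xt, depth, max_depth) {
  n <- nrow(xt)
  if (n <= 1 || depth >= max_depth) {
    pad <- if (n > 1) 2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n else 0
    return(rep(depth + pad, nrow(xq)))
  }
  j <- sample(ncol(xt), 1)
  rng <- range(xt[, j])
  if (rng[1] == rng[2]) return(rep(depth, nrow(xq)))
  split <- runif(1, rng[1], rng[2])
  left <- xq[, j] < split
  out <- numeric(nrow(xq))
  out[left] <- iso_tree_depth(xq[left, , drop = FALSE],
                              xt[xt[, j] < split, , drop = FALSE],
                              depth + 1, max_depth)
  out[!left] <- iso_tree_depth(xq[!left, , drop = FALSE],
                               xt[xt[, j] >= split, , drop = FALSE],
                               depth + 1, max_depth)
  out
}

#' Normalize counts to ln(CP10K+1)
#'
#' Scales each cell's counts to counts-per-10,000 and applies `log1p`:
#' value = ln(count * 10000 / cell_total + 1).
#'
#' @param matrix a filtered [count_matrix]; every cell must have >= 1 count.
#' @return An [expression_matrix] (sparse values).
#' @export
normalize_log_cp10k <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  totals <- Matrix::rowSums(matrix$counts)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  v <- Matrix::Diagonal(x = 1e4 / totals) %*% matrix$counts
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(matrix$counts)
  expression_matrix(v, matrix$cell_meta, matrix$gene_meta)
}

#' Quality-control reports: sex check and replicate concordance
#'
#' The sex check compares, per sequencing library (donor x replicate), the
#' pseudobulk CP10K of XIST to the mean pseudobulk CP10K of chromosome-Y
#' genes. When a cell-type annotation is supplied, replicate concordance is
#' the Pearson correlation of total-normalized pseudobulk profiles between
#' replicate pairs within donor x cell type x time x glucose arm.
#'
#' @param matrix a [count_matrix] whose `gene_meta` carries `chromosome`.
#' @param annotation optional per-cell cell-type labels (character vector
#'   aligned to cells, or an `annotation_result`).
#' @return list with `sex_check` (data.frame: sample, xist_cp10k,
#'   chry_cp10k, ratio) and `replicate_correlation` (data.frame or NULL).
#'   If XIST or chrY genes are absent, `sex_check` is NULL and
#'   `sex_check_available` is FALSE.
#' @export
qc_reports <- function(matrix, annotation = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  gm <- matrix$gene_meta
  cmeta <- matrix$cell_meta
  xist <- which(gm$symbol == "XIST")
  chry <- which(gm$chromosome == "Y")
  sample_id <- paste(cmeta$donor, cmeta$replicate, sep = "_")
  out <- list(sex_check_available = length(xist) == 1 && length(chry) > 0)
  if (out$sex_check_available) {
    sx <- lapply(split(seq_len(nrow(cmeta)), sample_id), function(idx) {
      tot <- sum(matrix$counts[idx, , drop = FALSE])
      pb <- Matrix::colSums(matrix$counts[idx, , drop = FALSE]) / tot * 1e4
      data.frame(xist_cp10k = pb[xist], chry_cp10k = mean(pb[chry]))
    })
    sex_check <- do.call(rbind, sx)
    sex_check$sample <- names(sx)
    sex_check$ratio <- sex_check$xist_cp10k / (sex_check$chry_cp10k + 1e-9)
    rownames(sex_check) <- NULL
    out$sex_check <- sex_check[, c("sample", "xist_cp10k", "chry_cp10k",
                                   "ratio")]
  } else {
    out["sex_check"] <- list(NULL)
  }
  out["replicate_correlation"] <- list(NULL)
  if (!is.null(annotation)) {
    labels <- if (inherits(annotation, "annotation_result"))
      annotation$cell_type else annotation
    stopifnot(length(labels) == nrow(cmeta))
    key <- paste(cmeta$donor, labels, cmeta$time_h, cmeta$glucose_arm,
                 sep = "|")
    rows <- lapply(split(seq_len(nrow(cmeta)), key), function(idx) {
      reps <- split(idx, cmeta$replicate[idx])
      if (length(reps) < 2) return(NULL)
      pb <- vapply(reps, function(i) {
        v <- Matrix::colSums(matrix$counts[i, , drop = FALSE])
        v / sum(v)
      }, numeric(ncol(matrix$counts)))
      pairs <- utils::combn(length(reps), 2)
      data.frame(
        stratum = paste(cmeta$donor[idx[1]], labels[idx[1]],
                        cmeta$time_h[idx[1]], cmeta$glucose_arm[idx[1]],
                        sep = "|"),
        rep_a = colnames(pb)[pairs[1, ]],
        rep_b = colnames(pb)[pairs[2, ]],
        pearson_r = apply(pairs, 2, function(p)
          stats::cor(pb[, p[1]], pb[, p[2]])))
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) > 0) {
      out$replicate_correlation <- do.call(rbind, rows)
      rownames(out$replicate_correlation) <- NULL
    }
  }
  out
}
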
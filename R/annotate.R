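#' Variable-gene selection, PCA and knee-based component selection
#'
#' Selects the `n_top_genes` most variable genes by per-sample dispersion
#' ranking followed by cross-sample frequency voting (a gene's vote count is
#' the number of samples in whose top list it appears; ties broken by mean
#' dispersion), mean-centers and unit-scales the selected ln(CP10K+1)
#' columns, runs PCA, and keeps the number of components at the knee of the
#' variance-explained scree curve.
#'
#' @param expr an [expression_matrix].
#' @param n_top_genes number of variable genes (all genes if fewer).
#' @param max_pcs maximum number of components to compute.
#' @param sample_id per-cell sample labels for the voting step; defaults to
#'   donor x replicate. With a single sample the vote degenerates to that
#'   sample's ranking.
#' @return list with `pcs` (cells x knee-selected components), `rotation`
#'   (variable genes x components loadings), `var_explained`, `n_pcs`,
#'   `var_genes`, and the centering/scaling vectors.
#' @export
embed_cells <- function(expr, n_top_genes = 2000, max_pcs = 30,
                        sample_id = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- as.matrix(expr$values)
  G <- ncol(v)
  n_top_genes <- min(n_top_genes, G)
  if (is.null(sample_id))
    sample_id <- paste(expr$cell_meta$donor, expr$cell_meta$replicate,
                       sep = "_")
  samples <- split(seq_len(nrow(v)), sample_id)
  disp <- function(idx) {
    m <- colMeans(v[idx, , drop = FALSE])
    s2 <- colMeans(v[idx, , drop = FALSE]^2) - m^2
    ifelse(m > 0, s2 / m, 0)  # dispersion = variance/mean on log scale
  }
  disp_all <- vapply(samples, disp, numeric(G))
  votes <- rowSums(apply(disp_all, 2, function(d)
    rank(-d, ties.method = "first") <= n_top_genes))
  mean_disp <- rowMeans(disp_all)
  ord <- order(-votes, -mean_disp)
  var_genes <- colnames(v)[ord[seq_len(n_top_genes)]]
  x <- v[, var_genes, drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  k <- min(max_pcs, nrow(x) - 1L, ncol(x))
  pc <- pca_fit(x, k)
  ve <- pc$var_explained
  n_pcs <- find_knee(seq_along(ve), ve)
  list(pcs = pc$scores[, seq_len(n_pcs), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve, n_pcs = n_pcs, var_genes = var_genes,
       center = ctr, scale = scl)
}

# PCA via eigen-decomposition of the gene-gene crossproduct (genes already
# centered); returns the leading k components.
pca_fit <- function(x, k) {
  n <- nrow(x)
  cp <- crossprod(x) / (n - 1)
  eig <- eigen(cp, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  rot <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(rot) <- colnames(x)
  colnames(rot) <- paste0("PC", seq_len(k))
  scores <- x %*% rot
  rownames(scores) <- rownames(x)
  list(scores = scores, rotation = rot,
       var_explained = vals[seq_len(k)] / sum(vals))
}

#' Knee point of a decreasing curve
#'
#' Normalizes x and y to the unit square and returns the index maximizing
#' the vertical distance between the flipped curve and the diagonal (the
#' standard kneedle construction for a decreasing convex curve).
#'
#' @param x,y coordinates of the curve (y decreasing).
#' @return Integer index of the knee (at least 1).
#' @export
find_knee <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  xn <- (x - min(x)) / (max(x) - min(x))
  yr <- max(y) - min(y)
  if (yr == 0) return(1L)
  yf <- (max(y) - y) / yr  # flipped: increasing 0..1
  which.max(yf - xn)
}

#' Per-class Matthews correlation coefficient
#'
#' One-vs-rest MCC for every class of a square confusion table (rows = true,
#' columns = predicted), computed from the closed form
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A class with a zero denominator (all-zero margin) is defined as 0.
#'
#' @param confusion square nonnegative integer matrix.
#' @return Named numeric vector of per-class MCC values in [-1, 1].
#' @export
compute_mcc <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0),
            sum(confusion) > 0)
  n <- sum(confusion)
  vapply(seq_len(nrow(confusion)), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- n - tp - fn - fp
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }, 0) -> mcc
  names(mcc) <- rownames(confusion) %||% as.character(seq_along(mcc))
  mcc
}

# Exact k-nearest-neighbor indices by blockwise Euclidean distance.
knn_indices <- function(x, k, block = 1024L) {
  n <- nrow(x)
  stopifnot(k < n)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  dists <- matrix(0, n, k)
  for (st in seq(1L, n, by = block)) {
    idx <- st:min(st + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    for (r in seq_along(idx)) {
      o <- order(d2[r, ])[seq_len(k)]
      out[idx[r], ] <- o
      dists[idx[r], ] <- sqrt(pmax(d2[r, o], 0))
    }
  }
  list(index = out, dist = dists)
}

#' Choose a clustering resolution by held-out classifier MCC
#'
#' For each resolution, clusters cells with the Leiden algorithm on a
#' k-nearest-neighbor graph of the embedding, trains a multinomial logistic
#' classifier (on the embedding coordinates) with a training split of the
#' cells, and computes per-cluster one-vs-rest MCC on the held-out third.
#' Returns the clustering at the largest resolution whose minimum
#' per-cluster test MCC exceeds `mcc_min`. A single-cluster solution counts
#' as passing (no confusion is possible). If no resolution passes, the
#' smallest resolution is returned with `warning_flag = TRUE`.
#'
#' @param embedding list from [embed_cells()] (or a bare matrix of cells x
#'   components).
#' @param resolutions numeric grid of Leiden resolutions (>= 2 values).
#' @param mcc_min minimum per-cluster MCC (default 0.75).
#' @param train_frac training fraction (default 2/3).
#' @param knn neighbors for the clustering graph.
#' @param seed RNG seed (split + Leiden refinement).
#' @return Object of class `annotation_result` (clusters only): list with
#'   `cluster` (factor per cell), `resolution`, `mcc_by_resolution`,
#'   `warning_flag`, `embedding`.
#' @export
resolution_sweep <- function(embedding, resolutions = c(0.05, 0.1, 0.25,
                                                        0.5, 1),
                             mcc_min = 0.75, train_frac = 2 / 3,
                             knn = 15, seed = 1) {
  pcs <- if (is.list(embedding)) embedding$pcs else embedding
  stopifnot(length(resolutions) >= 2)
  resolutions <- sort(resolutions)
  n <- nrow(pcs)
  nn <- knn_indices(pcs, min(knn, n - 1L))
  edges <- cbind(rep(seq_len(n), ncol(nn$index)), as.vector(nn$index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  sweep_rows <- list()
  clusterings <- list()
  for (i in seq_along(resolutions)) {
    r <- resolutions[i]
    cl <- with_seed(seed, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = r,
      n_iterations = 5))
    memb <- as.integer(igraph::membership(cl))
    clusterings[[i]] <- memb
    k <- length(unique(memb))
    if (k == 1) {
      min_mcc <- 1  # trivially perfect: nothing to confuse
      mccs <- c(`1` = 1)
    } else {
      split_idx <- with_seed(seed + 1,
                             sample(n, size = floor(train_frac * n)))
      fit <- nnet::multinom(
        cl ~ ., data = data.frame(cl = factor(memb[split_idx]),
                                  pcs[split_idx, , drop = FALSE]),
        trace = FALSE, MaxNWts = 100000, maxit = 200)
      test <- setdiff(seq_len(n), split_idx)
      pred <- predict(fit, newdata = data.frame(pcs[test, , drop = FALSE]))
      levs <- sort(unique(memb))
      conf <- table(factor(memb[test], levels = levs),
                    factor(pred, levels = levs))
      mccs <- compute_mcc(conf)
      min_mcc <- min(mccs)
    }
    sweep_rows[[i]] <- data.frame(resolution = r, n_clusters = k,
                                  min_mcc = min_mcc)
  }
  sweep_df <- do.call(rbind, sweep_rows)
  pass <- which(sweep_df$min_mcc > mcc_min)
  warning_flag <- length(pass) == 0
  chosen <- if (warning_flag) 1L else max(pass)
  if (warning_flag)
    warning("no resolution passed the MCC rule; returning the smallest")
  structure(list(
    cluster = factor(clusterings[[chosen]]),
    resolution = resolutions[chosen],
    mcc_by_resolution = sweep_df,
    warning_flag = warning_flag,
    embedding = if (is.list(embedding)) embedding else NULL),
    class = "annotation_result")
}

#' Label clusters with cell types from marker genes
#'
#' Each cluster is labeled with the cell type whose marker genes have the
#' highest mean standardized expression (z-score across cells) within the
#' cluster. Ties are broken by marker-gene count, then lexicographic type
#' name; tie-broken clusters are recorded.
#'
#' @param clusters factor/vector of per-cell cluster ids, or an
#'   `annotation_result`.
#' @param expr an [expression_matrix].
#' @param marker_table data.frame with columns `cell_type`, `gene_symbol`.
#' @return An `annotation_result` with `cell_type` per cell, `cluster_label`
#'   per cluster and `tie_broken` flags.
#' @export
assign_cell_types <- function(clusters, expr, marker_table) {
  res <- if (inherits(clusters, "annotation_result")) clusters else
    structure(list(cluster = factor(clusters)), class = "annotation_result")
  cl <- res$cluster
  v <- as.matrix(expr$values)
  present <- marker_table$gene_symbol %in% colnames(v)
  marker_table <- marker_table[present, , drop = FALSE]
  if (nrow(marker_table) == 0)
    stop("no marker genes present in the expression matrix")
  mk <- v[, marker_table$gene_symbol, drop = FALSE]
  mk <- scale(mk)
  mk[is.nan(mk)] <- 0
  types <- sort(unique(marker_table$cell_type))
  cluster_ids <- levels(cl)
  score <- matrix(NA_real_, length(cluster_ids), length(types),
                  dimnames = list(cluster_ids, types))
  for (ty in types) {
    cols <- marker_table$gene_symbol[marker_table$cell_type == ty]
    msub <- mk[, cols, drop = FALSE]
    score[, ty] <- vapply(cluster_ids, function(cid)
      mean(msub[cl == cid, , drop = FALSE]), 0)
  }
  n_markers <- vapply(types, function(ty)
    sum(marker_table$cell_type == ty), 0)
  tie_broken <- logical(length(cluster_ids))
  label <- character(length(cluster_ids))
  for (i in seq_along(cluster_ids)) {
    s <- score[i, ]
    best <- which(s == max(s))
    if (length(best) > 1) {
      tie_broken[i] <- TRUE
      nm <- n_markers[best]
      best <- best[nm == max(nm)]
      best <- best[order(types[best])][1]
    }
    label[i] <- types[best]
  }
  names(label) <- cluster_ids
  res$cluster_label <- label
  res$tie_broken <- setNames(tie_broken, cluster_ids)
  res$cell_type <- unname(label[as.character(cl)])
  res
}
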
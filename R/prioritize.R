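#' Gene x feature matrix for candidate-gene prioritization
#'
#' Assembles, per gene: global PCA gene loadings and per-cell-type PCA
#' loadings; one-vs-rest Welch t statistics per cell type with binary
#' up/down indicators at FDR < `fdr`; mean ln(CP10K+1) expression per cell
#' type; expression-specificity scores (each cell type's share of the
#' gene's summed per-type mean expression); and, for every supplied non-BvH
#' differential-expression result, the chi-square statistic and up/down
#' significance indicators. Genes absent from a component (e.g. prefiltered
#' out of a DGE family, or outside the variable-gene set) are zero-filled
#' and flagged. All columns are standardized (z-scored) at the end.
#'
#' @param expr an [expression_matrix].
#' @param annotation per-cell cell-type labels (character vector or
#'   `annotation_result`).
#' @param dge_results list of [run_design()] outputs (BvH entries are
#'   skipped).
#' @param embedding optional [embed_cells()] result for the global PC
#'   loadings (computed if NULL).
#' @param n_type_pcs components for the per-cell-type PCA blocks.
#' @param fdr threshold for the binary marker / DGE indicators.
#' @return Object of class `feature_matrix`: list with `features` (gene x
#'   feature numeric matrix), `groups` (feature group label per column),
#'   `imputed` (logical gene x group-level flags).
#' @export
build_feature_matrix <- function(expr, annotation, dge_results = list(),
                                 embedding = NULL, n_type_pcs = 5,
                                 fdr = 0.05) {
  labels <- if (inherits(annotation, "annotation_result"))
    annotation$cell_type else annotation
  stopifnot(length(labels) == nrow(expr$values))
  v <- as.matrix(expr$values)
  genes <- colnames(v)
  types <- sort(unique(labels))
  blocks <- list()
  groups <- character(0)

  add_block <- function(m, group) {
    blocks[[length(blocks) + 1]] <<- m
    groups <<- c(groups, rep(group, ncol(m)))
  }

  if (is.null(embedding))
    embedding <- embed_cells(expr, n_top_genes = min(2000, ncol(v)))
  rot <- matrix(0, length(genes), ncol(embedding$rotation),
                dimnames = list(genes, paste0("global_",
                                              colnames(embedding$rotation))))
  rot[rownames(embedding$rotation), ] <- embedding$rotation
  add_block(rot, "pc_global")

  for (ty in types) {
    idx <- which(labels == ty)
    if (length(idx) < n_type_pcs + 2) next
    x <- v[idx, , drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    keep <- scl > 0
    xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep],
                "/")
    k <- min(n_type_pcs, length(idx) - 1L, sum(keep))
    pc <- pca_fit(xs, k)
    m <- matrix(0, length(genes), k,
                dimnames = list(genes, paste0(ty, "_PC", seq_len(k))))
    m[rownames(pc$rotation), ] <- pc$rotation
    add_block(m, paste0("pc_", ty))
  }

  # one-vs-rest Welch t per cell type, vectorized over genes
  welch <- matrix(0, length(genes), length(types),
                  dimnames = list(genes, paste0("welch_t_", types)))
  up <- dn <- matrix(0, length(genes), length(types))
  colnames(up) <- paste0("marker_up_", types)
  colnames(dn) <- paste0("marker_down_", types)
  mean_expr <- matrix(0, length(genes), length(types),
                      dimnames = list(genes, paste0("mean_expr_", types)))
  for (j in seq_along(types)) {
    i1 <- labels == types[j]
    t_res <- welch_t_vec(v[i1, , drop = FALSE], v[!i1, , drop = FALSE])
    welch[, j] <- t_res$t
    qv <- bh_adjust(t_res$p)
    up[, j] <- as.numeric(qv < fdr & t_res$t > 0)
    dn[, j] <- as.numeric(qv < fdr & t_res$t < 0)
    mean_expr[, j] <- colMeans(v[i1, , drop = FALSE])
  }
  add_block(welch, "marker_t")
  add_block(up, "marker_up")
  add_block(dn, "marker_down")
  add_block(mean_expr, "mean_expr")

  tot <- rowSums(mean_expr)
  spec <- mean_expr / ifelse(tot > 0, tot, 1)
  colnames(spec) <- paste0("specificity_", types)
  add_block(spec, "specificity")

  imputed <- setNames(rep(FALSE, length(genes)), genes)
  for (d in dge_results) {
    if (attr(d, "design") == "BvH") next
    nm <- paste(attr(d, "cell_type"), attr(d, "design"),
                attr(d, "time_point") %||% "", sep = "_")
    m <- matrix(0, length(genes), 3,
                dimnames = list(genes, paste0(nm, c("_stat", "_up",
                                                    "_down"))))
    idx <- match(d$gene, genes)
    ok <- !is.na(idx)
    m[idx[ok], 1] <- ifelse(is.na(d$chisq[ok]), 0, d$chisq[ok])
    sig <- !is.na(d$q[ok]) & d$q[ok] < fdr
    m[idx[ok], 2] <- as.numeric(sig & d$sign[ok] > 0)
    m[idx[ok], 3] <- as.numeric(sig & d$sign[ok] < 0)
    imputed[setdiff(genes, d$gene)] <- TRUE
    add_block(m, paste0("dge_", nm))
  }

  f <- do.call(cbind, blocks)
  f[!is.finite(f)] <- 0  # declared 0-fill for untestable entries
  mu <- colMeans(f)
  s <- apply(f, 2, sd)
  s[s == 0] <- 1
  f <- sweep(sweep(f, 2, mu), 2, s, "/")
  structure(list(features = f, groups = groups, imputed = imputed),
            class = "feature_matrix")
}

# vectorized two-sample Welch t-test over columns
welch_t_vec <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) {
    G <- ncol(x1)
    return(list(t = rep(0, G), p = rep(1, G), df = rep(NA_real_, G)))
  }
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)),
                     1e-300)
  df[se2 == 0] <- 1  # degenerate constant gene; p overridden below
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  t[se2 == 0] <- 0
  p[se2 == 0] <- 1
  list(t = t, p = p, df = df)
}

# Ridge regression with the penalty chosen by generalized cross-validation
# on an SVD of the centered design; returns what is needed to re-fit
# cheaply for permuted responses.
ridge_gcv <- function(X, y, lambdas = 10^seq(-3, 4, length.out = 40)) {
  n <- nrow(X)
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  yb <- mean(y)
  yc <- y - yb
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  gcv <- vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- sv$u %*% (shrink * uty)
    rss <- sum((yc - fit)^2)
    edf <- sum(shrink)
    n * rss / (n - edf)^2
  }, 0)
  lambda <- lambdas[which.min(gcv)]
  shrink <- d2 / (d2 + lambda)
  beta <- sv$v %*% ((sv$d / (d2 + lambda)) * uty)
  fitted <- drop(sv$u %*% (shrink * uty)) + yb
  list(lambda = lambda, beta = drop(beta), intercept = yb, center = xc,
       fitted = fitted, svd = sv, shrink = shrink, gcv = gcv,
       lambdas = lambdas)
}

#' Priority scoring of candidate genes against association scores
#'
#' Fits a ridge-penalized linear regression (penalty chosen by generalized
#' cross-validation) of gene-level association scores on the standardized
#' feature matrix; a gene's priority score is its fitted value. The null is
#' built by permuting the feature-matrix gene identifiers `n_perm` times,
#' recomputing all priority scores at the same penalty, and pooling every
#' permuted score; the empirical p-value per gene is (r + 1) / (n + 1)
#' with r the number of pooled null scores >= the observed score and n the
#' pooled count. BH adjustment is applied across genes.
#'
#' @param features a `feature_matrix` (or bare gene x feature matrix with
#'   rownames).
#' @param scores data.frame with columns `gene_id`, `score` (e.g. gene-level
#'   association z-scores); genes are aligned by intersection with the
#'   feature rows.
#' @param n_perm number of identifier permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param fdr threshold stored alongside the results.
#' @return Object of class `priority_result`: data.frame with gene,
#'   priority_score, p, q, candidate (q < fdr), plus attributes `lambda`,
#'   `coefficients`, `n_perm`.
#' @export
pops_prioritize <- function(features, scores, n_perm = 10000, seed = 1,
                            fdr = 0.05) {
  f <- if (inherits(features, "feature_matrix")) features$features
  else as.matrix(features)
  stopifnot(n_perm >= 1, is.data.frame(scores),
            all(c("gene_id", "score") %in% names(scores)))
  if (sd(scores$score) == 0) stop("constant score vector")
  genes <- intersect(rownames(f), scores$gene_id)
  if (length(genes) < 2) stop("fewer than 2 genes shared between features and scores")
  X <- f[genes, , drop = FALSE]
  y <- scores$score[match(genes, scores$gene_id)]
  fit <- ridge_gcv(X, y)
  obs <- fit$fitted
  # permuting feature-row identifiers against fixed scores is equivalent to
  # permuting the response; re-fit at the selected penalty via the SVD
  u <- fit$svd$u
  shrink <- fit$shrink
  null_pool <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- y[sample(length(y))]
      ypc <- yp - mean(yp)
      drop(u %*% (shrink * crossprod(u, ypc))) + mean(yp)
    }, numeric(length(y)))
  })
  null_sorted <- sort(as.numeric(null_pool))
  n_pool <- length(null_sorted)
  # r = number of pooled null scores >= observed
  r <- n_pool - findInterval(obs - 1e-12, null_sorted)
  p <- (r + 1) / (n_pool + 1)
  q <- bh_adjust(p)
  out <- data.frame(gene = genes, priority_score = obs, p = p, q = q,
                    candidate = q < fdr, stringsAsFactors = FALSE)
  attr(out, "lambda") <- fit$lambda
  attr(out, "coefficients") <- setNames(fit$beta, colnames(X))
  attr(out, "n_perm") <- n_perm
  class(out) <- c("priority_result", "data.frame")
  out
}
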
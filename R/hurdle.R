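#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (thin wrapper over
#' `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value list")
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Median-CP10K gene prefilter
#'
#' Keeps genes whose median CP10K is at least 1 among the cells being
#' tested (genes with median CP10K < 1 are removed; the boundary value 1 is
#' retained).
#'
#' @param expr an [expression_matrix] (ln(CP10K+1) values) or bare matrix,
#'   already restricted to the tested cell subset.
#' @param threshold CP10K threshold (default 1).
#' @return Character vector of surviving gene ids (or column indices when
#'   unnamed).
#' @export
prefilter_genes <- function(expr, threshold = 1) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  med <- apply_sparse_median_cp10k(v)
  keep <- med >= threshold
  if (!any(keep)) stop("no genes survive the median-CP10K prefilter")
  if (!is.null(colnames(v))) colnames(v)[keep] else which(keep)
}

# column medians of expm1(values) without densifying the whole matrix
apply_sparse_median_cp10k <- function(v) {
  if (inherits(v, "sparseMatrix")) {
    v <- as(v, "CsparseMatrix")
    n <- nrow(v)
    vapply(seq_len(ncol(v)), function(j) {
      xs <- v@x[(v@p[j] + 1):v@p[j + 1]]
      nz <- length(xs)
      if (v@p[j] == v@p[j + 1]) return(0)
      if (nz <= n / 2) return(0)  # median over all cells hits a zero
      median(c(expm1(xs), rep(0, n - nz)))
    }, 0)
  } else {
    apply(expm1(as.matrix(v)), 2, median)
  }
}

# Ridge-penalized logistic regression by IRLS. Penalty applies to all
# coefficients (tiny by default; stabilizes near-separation). Returns the
# unpenalized log-likelihood at the estimate.
logistic_ridge <- function(X, z, ridge = 1e-6, max_iter = 50, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(ridge, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * wt) + pen
    g <- crossprod(X, z - mu) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  ll <- sum(z * eta - log1p(exp(eta)))
  list(beta = beta, ll = ll)
}

gaussian_fit <- function(X, y, ridge = 0) {
  n <- length(y)
  if (ridge > 0) {
    H <- crossprod(X) + diag(ridge, ncol(X))
    beta <- solve(H, crossprod(X, y))
  } else {
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
  }
  res <- y - drop(X %*% beta)
  sigma2 <- max(sum(res^2) / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(beta = drop(beta), sigma2 = sigma2, ll = ll)
}

#' Fit the two-part hurdle model for one gene
#'
#' Part 1 (discrete): ridge-stabilized logistic regression of the detection
#' indicator 1[y > 0] on the design matrix. Part 2 (continuous): Gaussian
#' linear regression of y on the design matrix restricted to cells with
#' y > 0. A part with no information (all-zero or all-nonzero gene for the
#' discrete part; no expressed cells for the continuous part) is marked dead
#' and contributes 0 degrees of freedom downstream. With fewer expressed
#' cells than coefficients + 2 the continuous part falls back to a ridge
#' fit and is flagged.
#'
#' @param y per-cell ln(CP10K+1) values for one gene (>= 0).
#' @param X design matrix (with intercept column).
#' @param ridge ridge penalty for the logistic part (and the continuous
#'   fallback), default 1e-6.
#' @return list with `disc` (`beta`, `ll`, `df`, `ok`), `cont` (`beta`,
#'   `sigma2`, `ll`, `df`, `ok`, `fallback`), and `n`.
#' @export
fit_hurdle <- function(y, X, ridge = 1e-6) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y >= 0))
  z <- as.numeric(y > 0)
  disc <- if (all(z == 0) || all(z == 1)) {
    list(beta = rep(NA_real_, ncol(X)), ll = 0, df = 0L, ok = FALSE)
  } else {
    f <- logistic_ridge(X, z, ridge)
    list(beta = setNames(f$beta, colnames(X)), ll = f$ll, df = ncol(X),
         ok = TRUE)
  }
  pos <- which(z == 1)
  if (length(pos) == 0) {
    cont <- list(beta = rep(NA_real_, ncol(X)), sigma2 = NA_real_, ll = 0,
                 df = 0L, ok = FALSE, fallback = FALSE)
  } else {
    fallback <- length(pos) < ncol(X) + 2
    f <- gaussian_fit(X[pos, , drop = FALSE], y[pos],
                      ridge = if (fallback) ridge else 0)
    cont <- list(beta = setNames(f$beta, colnames(X)), sigma2 = f$sigma2,
                 ll = f$ll, df = ncol(X), ok = TRUE, fallback = fallback)
  }
  list(disc = disc, cont = cont, n = length(y))
}

#' Likelihood-ratio test between nested hurdle fits
#'
#' Sums the 2*(ll_full - ll_reduced) statistics of the discrete and
#' continuous parts (a part enters only if live in both fits) and refers
#' the sum to a chi-square with the total number of dropped parameters
#' across live parts.
#'
#' @param full,reduced fits from [fit_hurdle()]; the reduced design must be
#'   nested in the full design.
#' @return list with `chisq`, `df`, `p`.
#' @export
lrt_hurdle <- function(full, reduced) {
  chisq <- 0; df <- 0L
  if (full$disc$ok && reduced$disc$ok) {
    if (full$disc$df < reduced$disc$df) stop("designs are not nested")
    chisq <- chisq + 2 * (full$disc$ll - reduced$disc$ll)
    df <- df + (full$disc$df - reduced$disc$df)
  }
  if (full$cont$ok && reduced$cont$ok) {
    if (full$cont$df < reduced$cont$df) stop("designs are not nested")
    chisq <- chisq + 2 * (full$cont$ll - reduced$cont$ll)
    df <- df + (full$cont$df - reduced$cont$df)
  }
  chisq <- max(chisq, 0)
  p <- if (df == 0) NA_real_ else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Hurdle differential-expression design
#'
#' @param name one of `"BvH"`, `"BvL"`, `"LvH"` (discrete; require
#'   `time_point`), `"time"`, `"glucose"`, `"time_glucose"` (continuous).
#' @param time_point compared time point (hours) for discrete designs.
#' @return An object of class `hurdle_design`.
#' @export
hurdle_design <- function(name = c("BvH", "BvL", "LvH", "time", "glucose",
                                   "time_glucose"), time_point = NULL) {
  name <- match.arg(name)
  discrete <- name %in% c("BvH", "BvL", "LvH")
  if (discrete && is.null(time_point))
    stop("discrete designs require a time point")
  structure(list(name = name, discrete = discrete, time_point = time_point),
            class = "hurdle_design")
}

# Build the cell subset, full design matrix, and reduced-model column drop
# for a design. Covariates: scaled cell complexity, donor indicators
# (constant columns dropped).
build_design <- function(meta, design, that_std = NULL) {
  arm <- meta$glucose_arm
  t <- meta$time_h
  if (design$discrete) {
    tp <- design$time_point
    cells <- switch(design$name,
      BvH = which((t == 0 & arm == "low") | (t == tp & arm == "high")),
      BvL = which((t == 0 & arm == "low") | (t == tp & arm == "low")),
      LvH = which(t == tp & (arm == "low" | arm == "high")))
    if (design$name == "BvL") {
      tested <- as.numeric(t[cells] == tp)
    } else {
      tested <- as.numeric(arm[cells] == "high")
    }
    if (length(unique(tested)) < 2) stop("a comparison group has zero cells")
    X <- cbind(`(Intercept)` = 1, tested = tested)
    inter <- NULL
  } else {
    cells <- which(t > 0)
    if (is.null(that_std)) stop("continuous designs require interpolated time")
    tt <- that_std[cells]
    hi <- as.numeric(arm[cells] == "high")
    X <- cbind(`(Intercept)` = 1, time = tt, glucose = hi)
    inter <- tt * hi
  }
  cplx <- meta$n_genes_detected[cells]
  cs <- sd(cplx)
  X <- cbind(X, complexity = if (cs > 0) (cplx - mean(cplx)) / cs else
    rep(0, length(cplx)))
  donors <- meta$donor[cells]
  du <- sort(unique(donors))
  if (length(du) > 1) {
    for (d in du[-1]) X <- cbind(X, as.numeric(donors == d))
    colnames(X)[(ncol(X) - length(du) + 2):ncol(X)] <-
      paste0("donor_", du[-1])
  }
  if (!is.null(inter) && design$name == "time_glucose")
    X <- cbind(X, `time:glucose` = inter)
  # drop aliased columns (keep the tested term's priority by construction)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keep)
    warning("dropping collinear design column(s): ",
            paste(colnames(X)[dropped], collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  tested_col <- switch(design$name,
    BvH = "tested", BvL = "tested", LvH = "tested",
    time = "time", glucose = "glucose", time_glucose = "time:glucose")
  if (!(tested_col %in% colnames(X)))
    stop("tested term was dropped as collinear; design is degenerate")
  list(cells = cells, X = X, tested_col = tested_col)
}

#' Run one hurdle differential-expression design
#'
#' Selects the design's cell subset (within one cell type when labels are
#' supplied), prefilters genes by median CP10K, fits the full and reduced
#' hurdle models per gene (the reduced model drops the tested term from
#' both parts), and attaches BH q-values within the (cell type, design)
#' family.
#'
#' @param expr an [expression_matrix].
#' @param design a [hurdle_design()].
#' @param cell_type,labels restrict to cells with `labels == cell_type`
#'   (both NULL = all cells).
#' @param that_std standardized interpolated time per cell of `expr`
#'   (required for continuous designs; ignored for discrete ones).
#' @param ridge logistic ridge penalty.
#' @param engine `"cpp"` (batched, default) or `"r"` (reference
#'   implementation; identical results within solver tolerance).
#' @return data.frame: gene, coef_disc, coef_cont, chisq, df, p, q, sign,
#'   with attributes `design`, `cell_type`, `n_cells`.
#' @export
run_design <- function(expr, design, cell_type = NULL, labels = NULL,
                       that_std = NULL, ridge = 1e-6,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(design, "hurdle_design"))
  meta <- expr$cell_meta
  keep <- if (!is.null(cell_type)) {
    stopifnot(length(labels) == nrow(meta))
    which(labels == cell_type)
  } else seq_len(nrow(meta))
  meta_sub <- meta[keep, , drop = FALSE]
  that_sub <- if (!is.null(that_std)) that_std[keep] else NULL
  d <- build_design(meta_sub, design, that_sub)
  cells <- keep[d$cells]
  v <- expr$values[cells, , drop = FALSE]
  genes <- prefilter_genes(expression_matrix(v, meta[cells, , drop = FALSE],
                                             expr$gene_meta))
  Y <- as.matrix(v[, genes, drop = FALSE])
  X <- d$X
  jt <- match(d$tested_col, colnames(X))
  if (engine == "cpp") {
    fit <- hurdle_batch_cpp(Y, X, jt, ridge)
    res <- data.frame(gene = genes, coef_disc = fit$coef_disc,
                      coef_cont = fit$coef_cont, chisq = fit$chisq,
                      df = as.integer(fit$df), p = fit$p)
  } else {
    Xr <- X[, -jt, drop = FALSE]
    rows <- lapply(seq_along(genes), function(g) {
      f <- fit_hurdle(Y[, g], X, ridge)
      r <- fit_hurdle(Y[, g], Xr, ridge)
      lr <- lrt_hurdle(f, r)
      data.frame(gene = genes[g],
                 coef_disc = unname(f$disc$beta[jt]),
                 coef_cont = unname(f$cont$beta[jt]),
                 chisq = lr$chisq, df = lr$df, p = lr$p)
    })
    res <- do.call(rbind, rows)
  }
  res$q <- bh_adjust(res$p)
  res$sign <- sign(ifelse(is.na(res$coef_cont) | res$coef_cont == 0,
                          ifelse(is.na(res$coef_disc), 0, res$coef_disc),
                          res$coef_cont))
  attr(res, "design") <- design$name
  attr(res, "time_point") <- design$time_point
  attr(res, "cell_type") <- cell_type %||% "all"
  attr(res, "n_cells") <- length(cells)
  res
}
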
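#' Interpolated time from explicit neighbor lists
#'
#' Evaluates t_hat = t*w + (sum(t_i/d_i) / sum(1/d_i)) * (1-w) for one cell
#' given its neighbor distances and sampled times. Distances below `eps` are
#' floored at `eps` so inverse-distance weights stay finite.
#'
#' @param t the cell's sampled time (hours).
#' @param w blend weight in [0, 1]; w = 1 returns `t` exactly.
#' @param d neighbor distances (positive).
#' @param tn neighbor sampled times (hours), same length as `d`.
#' @param eps zero-distance floor (default 1e-12).
#' @return The interpolated time t_hat.
#' @export
interpolated_time_formula <- function(t, w, d, tn, eps = 1e-12) {
  stopifnot(length(d) == length(tn), w >= 0, w <= 1)
  if (w == 1 || length(d) == 0) return(t)
  d <- pmax(d, eps)
  wi <- 1 / d
  t * w + sum(wi * tn) / sum(wi) * (1 - w)
}

#' Per-cell interpolated time within a cell type x glucose arm stratum
#'
#' For each cell in the stratum, finds its `n` nearest neighbors by
#' Euclidean distance in the knee-selected PC space of the stratum's
#' expression (or a caller-supplied coordinate space) and blends the cell's
#' sampled time with the inverse-distance-weighted mean of the neighbors'
#' sampled times. Cells sampled at 0 h must be excluded upstream.
#'
#' @param expr an [expression_matrix] restricted to one cell type and
#'   glucose arm (0 h removed), or a bare numeric matrix of coordinates.
#' @param times sampled time (hours) per cell.
#' @param n neighbor count (`n = 0` requires `w = 1` and returns `times`).
#' @param w blend weight in [0, 1].
#' @param space `"pca"` (embed the stratum, knee-selected components) or
#'   `"given"` (use `expr` as coordinates directly).
#' @param eps zero-distance floor.
#' @return data.frame with `t_sampled`, `t_hat_raw`, plus attributes `n`,
#'   `w`.
#' @export
interpolate_time <- function(expr, times, n = 75, w = 0.25,
                             space = c("pca", "given"), eps = 1e-12) {
  space <- match.arg(space)
  stopifnot(w >= 0, w <= 1, n >= 0)
  if (n == 0 && w < 1) stop("n = 0 requires w = 1 (no neighbors to average)")
  coords <- if (space == "pca") {
    emb <- embed_cells(expr, n_top_genes = min(2000, ncol(expr$values)))
    emb$pcs
  } else if (inherits(expr, "expression_matrix")) as.matrix(expr$values)
  else as.matrix(expr)
  stopifnot(nrow(coords) == length(times), n < nrow(coords))
  if (n == 0 || w == 1) {
    that <- times
  } else {
    nn <- knn_indices(coords, n)
    dmat <- pmax(nn$dist, eps)
    wmat <- 1 / dmat
    tmat <- matrix(times[nn$index], nrow(coords), n)
    that <- times * w + rowSums(wmat * tmat) / rowSums(wmat) * (1 - w)
  }
  out <- data.frame(t_sampled = times, t_hat_raw = that)
  attr(out, "n") <- n
  attr(out, "w") <- w
  out
}

#' Grid search for the neighbor count and blend weight
#'
#' For each `w`, computes interpolated time across the `n` grid and records
#' the mean squared difference between t_hat at consecutive `n` values as a
#' stability metric. Selects the smallest `n` after which every subsequent
#' step change stays below `tol_frac` times the largest step observed for
#' that `w`; the reported `n` is the maximum of the per-`w` selections at
#' the default `w`. The blend weight defaults to `default_w` (0.25); the
#' stability sweep is a diagnostic for `n`, while `w` trades concordance
#' with sampled time against power and is a judgment left to the caller.
#'
#' @param expr expression (or coordinates; see [interpolate_time()]).
#' @param times sampled times per cell.
#' @param n_grid neighbor grid (default 0 to 150 by 5, capped below the
#'   stratum size).
#' @param w_grid weight grid (default 0 to 1 by 0.25).
#' @param tol_frac stability tolerance as a fraction of the largest MSE
#'   step (default 0.05).
#' @param default_w returned `w` (default 0.25).
#' @param space coordinate space passed to [interpolate_time()].
#' @return list with `n`, `w`, and `stability` (data.frame: w, n_from,
#'   n_to, mse).
#' @export
select_interpolation_params <- function(expr, times,
                                        n_grid = seq(0, 150, by = 5),
                                        w_grid = seq(0, 1, by = 0.25),
                                        tol_frac = 0.05, default_w = 0.25,
                                        space = c("pca", "given")) {
  space <- match.arg(space)
  n_cells <- if (inherits(expr, "expression_matrix")) nrow(expr$values)
  else nrow(expr)
  n_grid <- n_grid[n_grid < n_cells]
  if (length(n_grid) < 2) stop("n grid must contain at least 2 usable values")
  coords <- if (space == "pca") {
    emb <- embed_cells(expr, n_top_genes = min(2000, ncol(expr$values)))
    emb$pcs
  } else if (inherits(expr, "expression_matrix")) as.matrix(expr$values)
  else as.matrix(expr)
  nmax <- max(n_grid)
  nn <- knn_indices(coords, max(nmax, 1))
  that_for <- function(n, w) {
    if (n == 0 || w == 1) return(times)  # n = 0: pure self time
    dmat <- pmax(nn$dist[, seq_len(n), drop = FALSE], 1e-12)
    wmat <- 1 / dmat
    tmat <- matrix(times[nn$index[, seq_len(n), drop = FALSE]],
                   length(times), n)
    times * w + rowSums(wmat * tmat) / rowSums(wmat) * (1 - w)
  }
  rows <- list()
  sel_n <- integer(0)
  for (w in w_grid) {
    prev <- that_for(n_grid[1], w)
    mses <- numeric(length(n_grid) - 1)
    for (i in 2:length(n_grid)) {
      cur <- that_for(n_grid[i], w)
      mses[i - 1] <- mean((cur - prev)^2)
      prev <- cur
    }
    rows[[length(rows) + 1]] <- data.frame(
      w = w, n_from = n_grid[-length(n_grid)], n_to = n_grid[-1], mse = mses)
    if (w == 1 || max(mses) == 0) {
      sel_n <- c(sel_n, n_grid[1])
    } else {
      thr <- tol_frac * max(mses)
      ok <- rev(cumprod(rev(mses <= thr))) == 1  # stable from here on
      first <- which(ok)[1]
      sel_n <- c(sel_n, if (is.na(first)) max(n_grid) else n_grid[first + 1])
    }
  }
  stability <- do.call(rbind, rows)
  use <- which(w_grid == default_w)
  n_sel <- if (length(use) == 1) sel_n[use] else max(sel_n)
  list(n = n_sel, w = default_w, stability = stability)
}

#' Standardize interpolated time to the unit interval within strata
#'
#' Linearly maps values to [0, 1] (min to 0, max to 1) independently within
#' each stratum (cell type x glucose arm). A constant stratum maps to 0.5
#' with a warning.
#'
#' @param that numeric vector of raw interpolated times.
#' @param stratum factor/vector of stratum labels (single stratum if NULL).
#' @return Numeric vector of standardized values in [0, 1].
#' @export
standardize_time <- function(that, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep(1L, length(that))
  out <- numeric(length(that))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    r <- range(that[idx])
    if (r[1] == r[2]) {
      warning("constant stratum in standardize_time; returning 0.5")
      out[idx] <- 0.5
    } else {
      out[idx] <- (that[idx] - r[1]) / (r[2] - r[1])
    }
  }
  out
}
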
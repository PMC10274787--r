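#' Genes entering module discovery
#'
#' Union of genes with q < `fdr` in any differential-expression design other
#' than BvH (whose contrast confounds glucose with time in culture and is
#' excluded from module selection).
#'
#' @param dge_results list of [run_design()] result data.frames for one cell
#'   type.
#' @param fdr FDR threshold (default 0.05).
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
select_module_genes <- function(dge_results, fdr = 0.05) {
  stopifnot(length(dge_results) >= 1)
  keep <- vapply(dge_results, function(d) attr(d, "design") != "BvH", TRUE)
  if (!any(keep)) stop("need at least one non-BvH design")
  hits <- lapply(dge_results[keep], function(d)
    d$gene[!is.na(d$q) & d$q < fdr])
  out <- sort(unique(unlist(hits)))
  if (length(out) == 0)
    warning("no genes pass FDR in any non-BvH design; skipping cell type")
  out
}

#' Smooth gene expression over interpolated time
#'
#' Fits, per gene and per glucose arm, a local polynomial (loess) regression
#' of ln(CP10K+1) on standardized interpolated time and evaluates it on the
#' 21-point grid 0, 0.05, ..., 1. Arms with fewer than 10 cells fall back to
#' a global linear fit and are flagged.
#'
#' @param expr an [expression_matrix] (cells at 0 h excluded upstream).
#' @param that_std standardized interpolated time per cell, in [0, 1].
#' @param arm per-cell glucose arm ("low"/"high").
#' @param genes gene ids to smooth.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return Object of class `smoothed_profiles`: list with `low` and `high`
#'   (gene x 21 matrices), `grid`, `span`, `fallback` flags.
#' @export
smooth_profiles <- function(expr, that_std, arm, genes, span = 0.75,
                            degree = 2) {
  v <- expr$values[, genes, drop = FALSE]
  stopifnot(nrow(v) == length(that_std), length(arm) == length(that_std),
            all(that_std >= 0 & that_std <= 1))
  grid <- seq(0, 1, by = 0.05)
  out <- list(grid = grid, span = span,
              fallback = setNames(logical(2), c("low", "high")))
  for (a in c("low", "high")) {
    idx <- which(arm == a)
    if (length(idx) == 0) stop("empty glucose arm stratum: ", a)
    tt <- that_std[idx]
    m <- matrix(NA_real_, length(genes), length(grid),
                dimnames = list(genes, grid))
    lin_fallback <- length(idx) < 10
    out$fallback[a] <- lin_fallback
    for (g in seq_along(genes)) {
      y <- as.numeric(v[idx, g])
      if (lin_fallback) {
        fit <- stats::lm(y ~ tt)
        m[g, ] <- stats::predict(fit, newdata = data.frame(tt = grid))
      } else {
        fit <- stats::loess(y ~ tt, span = span, degree = degree,
                            control = stats::loess.control(surface = "direct"))
        m[g, ] <- stats::predict(fit, newdata = data.frame(tt = grid))
      }
    }
    out[[a]] <- m
  }
  structure(out, class = "smoothed_profiles")
}

# z-score each gene's profile across the concatenated arm grids so that
# clustering groups genes by profile shape rather than expression level
standardize_profiles <- function(profiles) {
  x <- cbind(profiles$low, profiles$high)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  list(concat = z,
       low = z[, seq_len(ncol(profiles$low)), drop = FALSE],
       high = z[, -seq_len(ncol(profiles$low)), drop = FALSE])
}

se_kernel_eigen <- function(positions, blocks, lengthscales, sf2 = 1) {
  lapply(lengthscales, function(l) {
    d <- outer(positions, positions, "-")
    K <- sf2 * exp(-0.5 * (d / l)^2)
    K[outer(blocks, blocks, "!=")] <- 0  # arms are independent blocks
    K <- K + diag(1e-8, length(positions))
    e <- eigen(K, symmetric = TRUE)
    list(U = e$vectors, S = pmax(e$values, 0))
  })
}

#' Dirichlet-process Gaussian-process clustering of temporal profiles
#'
#' Gibbs sampling over a Dirichlet-process mixture of Gaussian processes
#' (squared-exponential kernel with a fixed length-scale grid resampled per
#' cluster, plus isotropic noise; auxiliary-cluster moves with `n_aux`
#' empty proposals per update). Returns the maximum-posterior sample as the
#' point clustering together with the posterior pairwise co-assignment
#' similarity matrix.
#'
#' @param profiles gene x grid matrix (rows are profiles, typically
#'   z-scored).
#' @param positions grid positions per column (defaults to an equispaced
#'   0-1 grid within each block).
#' @param blocks integer block label per column; the kernel is zero across
#'   blocks (used for concatenated low/high arms). Default: single block.
#' @param alpha Dirichlet-process concentration.
#' @param n_aux auxiliary empty clusters per Gibbs update.
#' @param n_iter total Gibbs sweeps; `burn` discarded (default half).
#' @param sn2 observation noise variance.
#' @param lengthscales squared-exponential length-scale grid (on the 0-1
#'   time scale).
#' @param sf2 kernel signal variance.
#' @param seed RNG seed.
#' @param init optional initial assignment vector (integer labels).
#' @return list with `assignments` (integer per gene, maximum-posterior
#'   sample), `similarity` (gene x gene co-assignment frequency),
#'   `loglik_trace`, `best_log_posterior`, `n_clusters`, and `converged`
#'   (likelihood-trace diagnostic; a warning is raised when FALSE).
#' @export
dpgp_cluster <- function(profiles, positions = NULL, blocks = NULL,
                         alpha = 1, n_aux = 4, n_iter = 100,
                         burn = floor(n_iter / 2), sn2 = 0.2,
                         lengthscales = c(0.1, 0.2, 0.4), sf2 = 1,
                         seed = 1, init = NULL) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 2)
  P <- ncol(profiles)
  if (is.null(blocks)) blocks <- rep(1L, P)
  if (is.null(positions)) {
    positions <- numeric(P)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      positions[idx] <- seq(0, 1, length.out = length(idx))
    }
  }
  eig <- se_kernel_eigen(positions, blocks, lengthscales, sf2)
  init_vec <- if (is.null(init)) integer(0) else as.integer(init)
  res <- with_seed(seed, dpgp_gibbs_cpp(
    profiles, lapply(eig, `[[`, "U"), lapply(eig, `[[`, "S"),
    sn2, alpha, as.integer(n_aux), as.integer(n_iter), as.integer(burn),
    init_vec))
  dimnames(res$similarity) <- list(rownames(profiles), rownames(profiles))
  res$assignments <- as.integer(res$assignments)
  names(res$assignments) <- rownames(profiles)
  res$loglik_trace <- as.numeric(res$loglik_trace)
  tr <- res$loglik_trace
  post <- tr[(burn + 1):length(tr)]
  half <- length(post) %/% 2
  res$converged <- TRUE
  if (half >= 2) {
    drift <- abs(mean(post[(half + 1):length(post)]) - mean(post[1:half]))
    spread <- max(sd(post), 1e-8)
    res$converged <- drift < 2 * spread
    if (!res$converged)
      warning("DPGP chain shows a drifting likelihood trace; ",
              "increase n_iter")
  }
  res
}

#' The default 45-configuration DPGP parameter grid
#'
#' Cross of 9 log-spaced concentration values (0.001 to 10) with 5
#' auxiliary-cluster counts (2, 4, 8, 12, 16).
#'
#' @return data.frame with columns `alpha`, `n_aux` (45 rows).
#' @export
dpgp_configs <- function() {
  expand.grid(alpha = 10^seq(-3, 1, length.out = 9),
              n_aux = c(2L, 4L, 8L, 12L, 16L))
}

#' Consensus matrix from DPGP runs over a configuration grid
#'
#' For each (alpha, n_aux) configuration: runs [dpgp_cluster()] separately
#' on the low-arm and high-arm profile grids, averages the two similarity
#' matrices (kept as a diagnostic), initializes a merged run on the
#' concatenated two-arm profiles from the point clustering of whichever arm
#' reached the higher posterior, and takes that merged run's clustering as
#' the configuration's result. The consensus entry for a gene pair is the
#' fraction of configurations in which the pair co-clusters. Failed
#' configurations are dropped from the denominator with a warning.
#'
#' @param profiles a `smoothed_profiles` object (or list with `low`/`high`
#'   gene x grid matrices sharing rownames). Profiles are z-scored across
#'   the concatenated grids before clustering.
#' @param configs data.frame of `alpha`, `n_aux` (default [dpgp_configs()]).
#' @param n_iter,sn2,lengthscales,sf2 passed to [dpgp_cluster()].
#' @param seed base seed; configuration i uses seed + i.
#' @return Object of class `consensus_matrix`: list with `consensus`
#'   (symmetric, unit diagonal), `n_configs`, `config_results`.
#' @export
consensus_from_runs <- function(profiles, configs = dpgp_configs(),
                                n_iter = 100, sn2 = 0.2,
                                lengthscales = c(0.1, 0.2, 0.4), sf2 = 1,
                                seed = 1) {
  stopifnot(identical(rownames(profiles$low), rownames(profiles$high)))
  zp <- standardize_profiles(profiles)
  G <- nrow(zp$concat)
  genes <- rownames(zp$concat)
  blocks2 <- rep(c(1L, 2L), c(ncol(zp$low), ncol(zp$high)))
  cooc <- matrix(0, G, G, dimnames = list(genes, genes))
  used <- 0L
  cfg_res <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    a <- configs$alpha[i]
    na <- configs$n_aux[i]
    ok <- TRUE
    res <- tryCatch({
      lo <- suppressWarnings(dpgp_cluster(zp$low, alpha = a, n_aux = na,
        n_iter = n_iter, sn2 = sn2, lengthscales = lengthscales, sf2 = sf2,
        seed = seed + 3L * i))
      hi <- suppressWarnings(dpgp_cluster(zp$high, alpha = a, n_aux = na,
        n_iter = n_iter, sn2 = sn2, lengthscales = lengthscales, sf2 = sf2,
        seed = seed + 3L * i + 1L))
      avg_sim <- (lo$similarity + hi$similarity) / 2
      init <- if (lo$best_log_posterior >= hi$best_log_posterior)
        lo$assignments else hi$assignments
      merged <- suppressWarnings(dpgp_cluster(zp$concat, blocks = blocks2,
        alpha = a, n_aux = na, n_iter = n_iter, sn2 = sn2,
        lengthscales = lengthscales, sf2 = sf2, seed = seed + 3L * i + 2L,
        init = init))
      list(assignments = merged$assignments, avg_similarity = avg_sim,
           merged = merged)
    }, error = function(e) {
      warning("DPGP configuration ", i, " failed: ", conditionMessage(e))
      ok <<- FALSE
      NULL
    })
    cfg_res[[i]] <- res
    if (ok) {
      used <- used + 1L
      same <- outer(res$assignments, res$assignments, "==")
      cooc <- cooc + same
    }
  }
  if (used == 0) stop("all DPGP configurations failed")
  consensus <- cooc / used
  diag(consensus) <- 1
  structure(list(consensus = consensus, n_configs = used,
                 config_results = cfg_res),
            class = "consensus_matrix")
}

#' Extract stable modules from a consensus matrix
#'
#' Iterative k-means on the consensus-matrix rows: starting at k = 2, k is
#' increased by 1 until at least one cluster's minimum pairwise
#' co-clustering frequency reaches `freq_min`; such clusters are removed,
#' k is decremented by the number removed, and the loop repeats until no
#' genes remain. Extracted clusters smaller than `min_size` are discarded
#' and their genes reported as unassigned.
#'
#' @param consensus a `consensus_matrix` or bare symmetric matrix in
#'   [0, 1].
#' @param freq_min minimum within-module co-clustering frequency (0.75).
#' @param min_size minimum module size (5).
#' @param seed k-means seeding.
#' @return Object of class `module_set`: list with `modules` (named list of
#'   gene-id vectors), `unassigned`, `membership` (named integer vector, NA
#'   for unassigned).
#' @export
extract_modules <- function(consensus, freq_min = 0.75, min_size = 5,
                            seed = 1) {
  C <- if (inherits(consensus, "consensus_matrix")) consensus$consensus
  else as.matrix(consensus)
  stopifnot(isSymmetric(unname(C)), all(C >= 0 & C <= 1))
  genes <- rownames(C) %||% as.character(seq_len(nrow(C)))
  rownames(C) <- colnames(C) <- genes
  remaining <- genes
  found <- list()
  k <- 2L
  with_seed(seed, {
    while (length(remaining) > 0) {
      sub <- C[remaining, remaining, drop = FALSE]
      if (length(remaining) == 1) {
        found[[length(found) + 1]] <- remaining
        remaining <- character(0)
        break
      }
      rows <- sub
      n_distinct <- nrow(unique(rows))
      kk <- min(k, length(remaining) - 1L, n_distinct)
      if (kk < 2) {
        cl <- rep(1L, length(remaining))
      } else {
        cl <- suppressWarnings(
          kmeans(rows, centers = kk, nstart = 10, iter.max = 100,
                 algorithm = "Lloyd"))$cluster
      }
      min_freq <- vapply(seq_len(max(cl)), function(c) {
        g <- which(cl == c)
        if (length(g) < 2) return(1)  # singleton: vacuously coherent
        min(sub[g, g])
      }, 0)
      pass <- which(min_freq >= freq_min)
      if (length(pass) > 0) {
        for (c in pass) found[[length(found) + 1]] <- remaining[cl == c]
        remaining <- remaining[!(cl %in% pass)]
        k <- max(k - length(pass), 2L)
      } else {
        k <- k + 1L
        if (k > length(remaining)) {
          # cannot split further; leave the rest unassigned
          break
        }
      }
    }
  })
  keep <- lengths(found) >= min_size
  modules <- found[keep]
  unassigned <- sort(c(remaining, unlist(found[!keep])))
  names(modules) <- if (length(modules)) paste0("module_",
                                                seq_along(modules)) else NULL
  membership <- setNames(rep(NA_integer_, length(genes)), genes)
  for (i in seq_along(modules)) membership[modules[[i]]] <- i
  structure(list(modules = modules, unassigned = unassigned,
                 membership = membership, freq_min = freq_min,
                 min_size = min_size),
            class = "module_set")
}

#' @export
#' @method print module_set
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules (sizes: %s), %d unassigned genes\n",
              length(x$modules),
              paste(lengths(x$modules), collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}

#' Discover co-expression modules for one cell type
#'
#' Wires together gene selection ([select_module_genes()]), per-arm loess
#' smoothing over interpolated time ([smooth_profiles()]), the
#' 45-configuration DPGP consensus ([consensus_from_runs()]), and stable
#' module extraction ([extract_modules()]). Returns per-module mean
#' profiles per arm alongside the assignments.
#'
#' @param expr an [expression_matrix] restricted to one cell type with 0 h
#'   cells removed.
#' @param that_std standardized interpolated time per cell.
#' @param arm glucose arm per cell.
#' @param dge_results list of [run_design()] outputs for this cell type.
#' @param fdr selection FDR.
#' @param max_genes cap on genes entering clustering (most significant
#'   kept, by minimum q across designs).
#' @param configs,n_iter,seed passed to [consensus_from_runs()].
#' @param freq_min,min_size passed to [extract_modules()].
#' @return A `module_set` with extra fields `profiles` (smoothed),
#'   `consensus`, and `module_profiles` (list of per-arm mean profile
#'   matrices).
#' @export
discover_modules <- function(expr, that_std, arm, dge_results, fdr = 0.05,
                             max_genes = 150, configs = dpgp_configs(),
                             n_iter = 100, seed = 1, freq_min = 0.75,
                             min_size = 5) {
  genes <- select_module_genes(dge_results, fdr)
  if (length(genes) < 2) stop("fewer than 2 genes selected for clustering")
  if (length(genes) > max_genes) {
    minq <- rep(Inf, length(genes))
    for (d in dge_results) {
      if (attr(d, "design") == "BvH") next
      m <- match(genes, d$gene)
      qv <- d$q[m]
      minq <- pmin(minq, ifelse(is.na(qv), Inf, qv))
    }
    genes <- genes[order(minq)][seq_len(max_genes)]
  }
  prof <- smooth_profiles(expr, that_std, arm, genes)
  cons <- consensus_from_runs(prof, configs = configs, n_iter = n_iter,
                              seed = seed)
  mods <- extract_modules(cons, freq_min = freq_min, min_size = min_size,
                          seed = seed)
  mods$profiles <- prof
  mods$consensus <- cons$consensus
  mods$module_profiles <- lapply(mods$modules, function(g)
    list(low = colMeans(prof$low[g, , drop = FALSE]),
         high = colMeans(prof$high[g, , drop = FALSE])))
  mods
}
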
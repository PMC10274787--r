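make_labeled_expr <- function() {
  set.seed(22)
  n <- 90
  labels <- rep(c("alpha", "beta", "delta"), each = n / 3)
  v <- matrix(abs(rnorm(n * 12, 1, 0.3)), n, 12)
  colnames(v) <- paste0("g", 1:12)
  v[labels == "beta", "g1"] <- v[labels == "beta", "g1"] + 2  # beta marker
  v[labels != "beta", "g2"] <- 0                              # beta-only gene
  v[labels == "beta", "g2"] <- 1.5
  expr <- expression_matrix(v, data.frame(cell_id = paste0("c", 1:n),
                                          donor = "d1", replicate = "r1"),
                            data.frame(gene_id = colnames(v)))
  list(expr = expr, labels = labels)
}

test_that("feature matrix encodes specificity, markers and DGE blocks", {
  x <- make_labeled_expr()
  fm <- build_feature_matrix(x$expr, x$labels, n_type_pcs = 2)
  f <- fm$features
  expect_equal(nrow(f), 12)
  expect_false(any(!is.finite(f)))
  # columns standardized
  expect_true(all(abs(colMeans(f)) < 1e-10))
  # exclusive expression: specificity ~ 1 for beta, ~ 0 elsewhere (raw scale)
  raw_spec <- vapply(c("alpha", "beta", "delta"), function(ty)
    mean(x$expr$values[x$labels == ty, "g2"]), 0)
  expect_equal(unname(raw_spec["beta"] / sum(raw_spec)), 1)
  # planted marker has the largest Welch t within its marker group
  welch_cols <- which(fm$groups == "marker_t")
  beta_col <- grep("beta", colnames(f)[welch_cols])
  tvals <- f[, welch_cols[beta_col]]
  expect_equal(names(which.max(tvals)), "g1")
  # two identical cell types: Welch t about 0
  set.seed(23)
  v2 <- matrix(rnorm(60 * 5, 2), 60, 5,
               dimnames = list(paste0("c", 1:60), paste0("h", 1:5)))
  expr2 <- expression_matrix(abs(v2),
                             data.frame(cell_id = rownames(v2),
                                        donor = "d1", replicate = "r1"),
                             data.frame(gene_id = colnames(v2)))
  t2 <- glucodyn:::welch_t_vec(abs(v2)[1:30, ], abs(v2)[31:60, ])
  expect_true(all(abs(t2$t) < 3))
  expect_gt(min(t2$p), 0.001)
  # DGE block zero-fills untested genes and flags them
  d <- data.frame(gene = c("g1", "g3"), coef_disc = 0, coef_cont = c(1, -1),
                  chisq = c(9, 16), df = 2, p = c(0.001, 0.0001),
                  q = c(0.01, 0.001), sign = c(1, -1))
  attr(d, "design") <- "LvH"; attr(d, "time_point") <- 8
  attr(d, "cell_type") <- "beta"
  fm2 <- build_feature_matrix(x$expr, x$labels, dge_results = list(d),
                              n_type_pcs = 2)
  expect_true(any(grepl("beta_LvH_8", colnames(fm2$features))))
  expect_true(fm2$imputed[["g2"]])
  expect_false(fm2$imputed[["g1"]])
})

test_that("empirical p equals direct counting at small n_perm", {
  set.seed(24)
  G <- 40
  X <- matrix(rnorm(G * 5), G, 5,
              dimnames = list(paste0("g", 1:G), paste0("f", 1:5)))
  sc <- data.frame(gene_id = rownames(X), score = rnorm(G))
  n_perm <- 50
  pr <- pops_prioritize(X, sc, n_perm = n_perm, seed = 9)
  # rebuild the identical null pool by replaying the permutations
  f <- scale(X, scale = FALSE)
  y <- sc$score[match(pr$gene, sc$gene_id)]
  fit <- glucodyn:::ridge_gcv(X[pr$gene, ], y)
  pool <- glucodyn:::with_seed(9, {
    vapply(seq_len(n_perm), function(b) {
      yp <- y[sample(length(y))]
      ypc <- yp - mean(yp)
      drop(fit$svd$u %*% (fit$shrink * crossprod(fit$svd$u, ypc))) + mean(yp)
    }, numeric(length(y)))
  })
  pool <- as.numeric(pool)
  r_direct <- vapply(fit$fitted, function(o) sum(pool >= o), 0)
  expect_equal(pr$p, (r_direct + 1) / (length(pool) + 1), tolerance = 1e-12)
  expect_true(all(pr$p >= 1 / (length(pool) + 1)))
  expect_true(all(pr$p <= 1))
})

test_that("ridge GCV agrees with an independent implementation", {
  set.seed(25)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- X[, 1] - 2 * X[, 2] + rnorm(200)
  fit <- glucodyn:::ridge_gcv(X, y, lambdas = c(0.1, 1, 10))
  ref <- MASS::lm.ridge(y ~ X, lambda = c(0.1, 1, 10))
  # same GCV ordering (scales differ by constants)
  expect_equal(order(fit$gcv), order(ref$GCV))
  # coefficients at the chosen penalty match a direct normal-equations solve
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  direct <- solve(crossprod(Xc) + diag(fit$lambda, ncol(X)),
                  crossprod(Xc, yc))
  expect_equal(unname(fit$beta), unname(drop(direct)), tolerance = 1e-8)
})

test_that("planted feature signal is recovered and nulls stay empty", {
  set.seed(26)
  G <- 1000
  X <- matrix(rnorm(G * 20), G, 20,
              dimnames = list(paste0("g", 1:G), paste0("f", 1:20)))
  beta <- c(3, -2, 1.5, rep(0, 17))
  truth_score <- drop(X %*% beta)
  sc <- data.frame(gene_id = rownames(X), score = truth_score + rnorm(G))
  pr <- pops_prioritize(X, sc, n_perm = 500, seed = 2)
  co <- attr(pr, "coefficients")
  expect_setequal(names(sort(-abs(co)))[1:3], c("f1", "f2", "f3"))
  top_true <- rownames(X)[rank(-truth_score) <= G / 10]
  top_obs <- pr$gene[rank(-pr$priority_score) <= G / 10]
  k <- length(intersect(top_true, top_obs))
  p_enrich <- phyper(k - 1, G / 10, G - G / 10, G / 10, lower.tail = FALSE)
  expect_lt(p_enrich, 1e-6)
  # independent scores: essentially no discoveries
  sc0 <- data.frame(gene_id = rownames(X), score = rnorm(G))
  pr0 <- pops_prioritize(X, sc0, n_perm = 500, seed = 2)
  expect_lte(sum(pr0$q < 0.05), 2)
  expect_error(pops_prioritize(X, data.frame(gene_id = rownames(X),
                                             score = 1), n_perm = 10),
               "constant")
})

test_that("priority scores are invariant to feature order and rescaling", {
  set.seed(27)
  G <- 200
  X <- matrix(rnorm(G * 6), G, 6,
              dimnames = list(paste0("g", 1:G), paste0("f", 1:6)))
  sc <- data.frame(gene_id = rownames(X), score = X[, 1] + rnorm(G))
  base <- pops_prioritize(X, sc, n_perm = 20, seed = 3)
  perm <- sample(6)
  pr2 <- pops_prioritize(X[, perm], sc, n_perm = 20, seed = 3)
  expect_equal(pr2$priority_score, base$priority_score, tolerance = 1e-9)
  # affine rescaling of a column is removed by standardization
  Xs <- X
  Xs[, 2] <- 5 * Xs[, 2] - 7
  Xz <- scale(Xs)
  Xz0 <- scale(X)
  attr(Xz, "scaled:center") <- attr(Xz, "scaled:scale") <- NULL
  attr(Xz0, "scaled:center") <- attr(Xz0, "scaled:scale") <- NULL
  pr3 <- pops_prioritize(Xz, sc, n_perm = 20, seed = 3)
  pr4 <- pops_prioritize(Xz0, sc, n_perm = 20, seed = 3)
  expect_equal(pr3$priority_score, pr4$priority_score, tolerance = 1e-9)
})
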
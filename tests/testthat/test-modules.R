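fake_dge <- function(genes, q, design, cell_type = "beta",
                     time_point = NULL) {
  d <- data.frame(gene = genes, coef_disc = 0, coef_cont = 1, chisq = 1,
                  df = 2, p = q, q = q, sign = 1)
  attr(d, "design") <- design
  attr(d, "time_point") <- time_point
  attr(d, "cell_type") <- cell_type
  d
}

test_that("module gene selection excludes BvH and applies the threshold", {
  bvh <- fake_dge(c("a", "b"), c(0.001, 0.2), "BvH", time_point = 8)
  lvh <- fake_dge(c("b", "c"), c(0.049, 0.051), "LvH", time_point = 8)
  tim <- fake_dge(c("d"), 0.01, "time")
  sel <- select_module_genes(list(bvh, lvh, tim))
  expect_setequal(sel, c("b", "d"))       # a: BvH-only -> excluded
  expect_false("c" %in% sel)              # q = 0.051 -> excluded
  expect_error(select_module_genes(list(bvh)), "non-BvH")
  expect_warning(select_module_genes(list(fake_dge("x", 0.9, "LvH", 8))),
                 "no genes pass")
})

test_that("loess smoothing preserves constants and exact linear trends", {
  set.seed(16)
  n <- 200
  tt <- runif(n)
  arm <- rep(c("low", "high"), each = n / 2)
  v <- cbind(const = rep(2.5, n), lin = 2 * tt,
             noisy = 2 + sin(2 * pi * tt) + rnorm(n, 0, 0.2))
  expr <- expression_matrix(v, data.frame(cell_id = paste0("c", 1:n)),
                            data.frame(gene_id = colnames(v)))
  prof <- smooth_profiles(expr, tt, arm, colnames(v))
  expect_equal(dim(prof$low), c(3, 21))
  expect_equal(unname(prof$low["const", ]), rep(2.5, 21), tolerance = 1e-9)
  expect_equal(unname(prof$high["lin", ]), 2 * prof$grid, tolerance = 1e-6)
  expect_lt(max(abs(prof$low["noisy", ] -
                      (2 + sin(2 * pi * prof$grid)))), 0.35)
  # < 10 cells in an arm falls back to a global linear fit with a flag
  small <- expression_matrix(v[1:12, ],
                             data.frame(cell_id = paste0("c", 1:12)),
                             data.frame(gene_id = colnames(v)))
  prof2 <- smooth_profiles(small, tt[1:12], rep(c("low", "high"), c(8, 4)),
                           colnames(v))
  expect_true(prof2$fallback[["high"]])
})

test_that("DPGP separates shapes, merges replicates, and is deterministic", {
  set.seed(17)
  grid <- seq(0, 1, by = 0.05)
  up <- t(sapply(1:15, function(i) 2 * grid - 1 + rnorm(21, 0, 0.1)))
  down <- t(sapply(1:15, function(i) 1 - 2 * grid + rnorm(21, 0, 0.1)))
  Y <- rbind(up, down)
  rownames(Y) <- paste0("g", 1:30)
  r <- dpgp_cluster(Y, n_iter = 80, seed = 2)
  expect_equal(r$n_clusters, 2)
  expect_true(all(r$similarity[1:15, 1:15] > 0.9))
  expect_true(all(r$similarity[1:15, 16:30] < 0.1))
  expect_true(all(diag(r$similarity) == 1))
  expect_true(isSymmetric(unname(r$similarity)))
  # homogeneous profiles collapse to one dominant cluster
  hom <- t(sapply(1:20, function(i) sin(2 * pi * grid) + rnorm(21, 0, 0.1)))
  r2 <- dpgp_cluster(hom, n_iter = 80, seed = 2)
  expect_gte(max(table(r2$assignments)) / 20, 0.9)
  # determinism and split-chain similarity agreement on the separable case
  r3 <- dpgp_cluster(Y, n_iter = 80, seed = 2)
  expect_identical(r$assignments, r3$assignments)
  r4 <- dpgp_cluster(Y, n_iter = 80, seed = 99)
  expect_lt(mean(abs(r$similarity - r4$similarity)), 0.1)
})

test_that("DPGP recovers three planted shapes at high accuracy", {
  set.seed(18)
  grid <- seq(0, 1, by = 0.05)
  shapes <- list(function(t) 2 * t - 1, function(t) 1 - 2 * t,
                 function(t) sin(2 * pi * t))
  Y <- do.call(rbind, lapply(shapes, function(f)
    t(sapply(1:20, function(i) f(grid) + rnorm(21, 0, 0.25)))))
  rownames(Y) <- paste0("g", 1:60)
  truth <- rep(1:3, each = 20)
  r <- dpgp_cluster(Y, alpha = 1, n_iter = 100, seed = 4)
  expect_gte(ari_contingency(r$assignments, truth), 0.9)
})

test_that("consensus counting and invariants hold", {
  set.seed(19)
  grid <- seq(0, 1, by = 0.05)
  mk <- function(f, n, noise) t(sapply(1:n, function(i)
    f(grid) + rnorm(21, 0, noise)))
  prof <- list(
    low = rbind(mk(function(t) 2.5 * t, 10, 0.2),
                mk(function(t) rep(0, 21), 10, 0.2)),
    high = rbind(mk(function(t) 2.5 * t, 10, 0.2),
                 mk(function(t) rep(2.5, 21), 10, 0.2)))
  rownames(prof$low) <- rownames(prof$high) <- paste0("g", 1:20)
  cons <- consensus_from_runs(prof, configs = dpgp_configs()[c(5, 23, 41), ],
                              n_iter = 60, seed = 1)
  C <- cons$consensus
  expect_true(isSymmetric(unname(C)))
  expect_equal(unname(diag(C)), rep(1, 20))
  expect_true(all(C >= 0 & C <= 1))
  # entries are multiples of 1/n_configs (co-clustering frequencies)
  off <- C[upper.tri(C)]
  expect_true(all(abs(off * cons$n_configs -
                        round(off * cons$n_configs)) < 1e-9))
  # cleanly separated shapes agree across all configurations
  expect_true(all(C[1:10, 1:10] == 1))
  expect_true(all(C[1:10, 11:20] == 0))
})

test_that("module extraction handles exact, undersized and noisy blocks", {
  # two exact blocks
  C <- matrix(0, 20, 20)
  C[1:10, 1:10] <- 1
  C[11:20, 11:20] <- 1
  rownames(C) <- colnames(C) <- paste0("x", 1:20)
  ms <- extract_modules(C)
  expect_equal(unname(sort(lengths(ms$modules))), c(10L, 10L))
  expect_setequal(ms$modules[[ms$membership[["x1"]]]], paste0("x", 1:10))
  # a perfect 4-gene block is extracted then discarded by min_size
  C2 <- matrix(0, 9, 9)
  C2[1:4, 1:4] <- 1
  C2[5:9, 5:9] <- 1
  rownames(C2) <- colnames(C2) <- paste0("y", 1:9)
  ms2 <- extract_modules(C2, min_size = 5)
  expect_equal(unname(lengths(ms2$modules)), 5L)
  expect_setequal(ms2$unassigned, paste0("y", 1:4))
  # noisy planted blocks recovered exactly over seeds
  set.seed(20)
  for (s in 1:5) {
    Cn <- matrix(runif(30 * 30, 0, 0.1), 30, 30)
    for (b in 0:2) Cn[b * 10 + 1:10, b * 10 + 1:10] <-
      runif(100, 0.85, 1)
    Cn <- (Cn + t(Cn)) / 2
    diag(Cn) <- 1
    rownames(Cn) <- colnames(Cn) <- paste0("z", 1:30)
    msn <- extract_modules(Cn, seed = s)
    expect_equal(unname(sort(lengths(msn$modules))), rep(10L, 3))
    expect_equal(length(msn$unassigned), 0)
  }
  # gene-order invariance (up to module relabeling)
  perm <- sample(20)
  msp <- extract_modules(C[perm, perm])
  expect_equal(ari_contingency(msp$membership[rownames(C)],
                               ms$membership[rownames(C)]), 1)
  # modules satisfy their invariants on a mixed consensus
  expect_true(all(vapply(ms$modules, function(g) min(C[g, g]) >= 0.75, TRUE)))
})

test_that("all modules from noisy consensus satisfy frequency and size", {
  set.seed(21)
  Cn <- matrix(runif(40 * 40, 0, 0.5), 40, 40)
  Cn[1:12, 1:12] <- runif(144, 0.8, 1)
  Cn <- (Cn + t(Cn)) / 2
  diag(Cn) <- 1
  rownames(Cn) <- colnames(Cn) <- paste0("w", 1:40)
  ms <- extract_modules(Cn, freq_min = 0.75, min_size = 5)
  for (g in ms$modules) {
    expect_gte(length(g), 5)
    expect_gte(min(Cn[g, g]), 0.75)
  }
  # modules are disjoint
  expect_equal(anyDuplicated(unlist(ms$modules)), 0)
})
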
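test_that("knee selection matches a brute-force chord construction", {
  # decreasing convex curve with a sharp elbow, then flat tail
  y <- c(10, 5, 2.5, 1.25, rep(1.2, 8))
  x <- seq_along(y)
  # oracle: normalize both axes, flip y, maximal distance above the diagonal
  xn <- (x - min(x)) / diff(range(x))
  yf <- (max(y) - y) / diff(range(y))
  oracle <- which.max(yf - xn)
  expect_equal(find_knee(x, y), oracle)
  expect_equal(find_knee(x, rep(1, 12)), 1L)
})

test_that("PCA component count tracks planted rank", {
  set.seed(3)
  n <- 400
  k <- 3
  signal <- matrix(rnorm(n * k, sd = 6), n, k) %*% matrix(rnorm(k * 60), k, 60)
  x <- signal + matrix(rnorm(n * 60), n, 60)
  x <- x - min(x)  # nonnegative shift leaves the covariance untouched
  colnames(x) <- paste0("g", 1:60)
  rownames(x) <- paste0("c", 1:n)
  meta <- data.frame(cell_id = rownames(x), donor = "d1", replicate = "r1")
  expr <- expression_matrix(x, meta, data.frame(gene_id = colnames(x)))
  emb <- embed_cells(expr, n_top_genes = 60)
  expect_true(abs(emb$n_pcs - k) <= 1)
})

test_that("variable-gene voting degenerates to the single sample's ranking", {
  set.seed(4)
  x <- matrix(abs(rnorm(100 * 50)), 100, 50)
  x[, 1:10] <- x[, 1:10] * 5  # high-dispersion genes
  colnames(x) <- paste0("g", 1:50)
  meta <- data.frame(cell_id = paste0("c", 1:100), donor = "d1",
                     replicate = "r1")
  expr <- expression_matrix(x, meta, data.frame(gene_id = colnames(x)))
  emb <- embed_cells(expr, n_top_genes = 10)
  disp <- apply(x, 2, var) / colMeans(x)
  expect_setequal(emb$var_genes, names(sort(-disp))[1:10])
})

test_that("MCC matches the closed form and brute-force on random tables", {
  expect_equal(unname(compute_mcc(diag(c(5, 3, 7)))), rep(1, 3))
  anti <- matrix(c(0, 4, 6, 0), 2, 2)
  expect_equal(unname(compute_mcc(anti)), c(-1, -1))
  conf <- matrix(c(40, 10, 10, 140), 2, 2, byrow = TRUE)
  expect_equal(unname(compute_mcc(conf))[1],
               (40 * 140 - 10 * 10) / sqrt(50 * 50 * 150 * 150))
  # degenerate class margin -> 0
  degen <- rbind(c(5, 0), c(0, 0))
  expect_equal(unname(compute_mcc(degen))[2], 0)
  # property: agree with an explicit TP/FP/TN/FN enumeration
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(k * k, 5), k, k)
    if (sum(tab) == 0) next
    got <- compute_mcc(tab)
    for (c in seq_len(k)) {
      tp <- tab[c, c]; fn <- sum(tab[c, ]) - tp
      fp <- sum(tab[, c]) - tp; tn <- sum(tab) - tp - fn - fp
      den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
        sqrt((tn + fn))
      want <- if (den == 0) 0 else (tp * tn - fp * fn) / den
      expect_equal(unname(got[c]), want, tolerance = 1e-12)
    }
  }
})

test_that("resolution sweep recovers planted blob structure", {
  set.seed(6)
  n_per <- 120
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  pcs <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, centers[i, 1]), rnorm(n_per, centers[i, 2]))))
  pcs <- cbind(pcs, matrix(rnorm(3 * n_per * 6), ncol = 6))  # noise dims
  ann <- resolution_sweep(pcs, resolutions = c(0.05, 0.1, 0.25, 0.5, 1),
                          seed = 1)
  expect_equal(length(unique(ann$cluster)), 3)
  expect_false(ann$warning_flag)
  expect_true(ann$resolution %in% c(0.05, 0.1, 0.25, 0.5, 1))
  # a homogeneous blob: splitting resolutions fail the MCC rule
  blob <- cbind(matrix(rnorm(600), 300, 2),
                matrix(rnorm(300 * 6), 300, 6))
  ann2 <- resolution_sweep(blob, resolutions = c(0.1, 0.5, 1), seed = 1)
  tab <- ann2$mcc_by_resolution
  expect_true(all(tab$min_mcc[tab$n_clusters > 1] <= 0.75))
  # determinism
  ann3 <- resolution_sweep(pcs, resolutions = c(0.05, 0.1, 0.25, 0.5, 1),
                           seed = 1)
  expect_identical(ann$cluster, ann3$cluster)
  expect_identical(ann$resolution, ann3$resolution)
})

test_that("marker assignment labels clusters and breaks ties predictably", {
  set.seed(7)
  n <- 60
  v <- matrix(abs(rnorm(2 * n * 4, 0.1)), 2 * n, 4)
  colnames(v) <- c("INS", "GCG", "SST", "other")
  v[1:n, "INS"] <- 5
  v[(n + 1):(2 * n), "GCG"] <- 5
  meta <- data.frame(cell_id = paste0("c", 1:(2 * n)), donor = "d1",
                     replicate = "r1")
  expr <- expression_matrix(v, meta, data.frame(gene_id = colnames(v)))
  markers <- data.frame(cell_type = c("beta", "alpha", "delta"),
                        gene_symbol = c("INS", "GCG", "SST"))
  clusters <- rep(c(1, 2), each = n)
  ann <- assign_cell_types(clusters, expr, markers)
  expect_equal(unname(ann$cluster_label[c("1", "2")]), c("beta", "alpha"))
  # gene/cell order invariance
  perm_g <- c(3, 1, 4, 2)
  perm_c <- sample(2 * n)
  expr2 <- expression_matrix(v[perm_c, perm_g], meta[perm_c, ],
                             data.frame(gene_id = colnames(v)[perm_g]))
  ann2 <- assign_cell_types(clusters[perm_c], expr2, markers)
  expect_equal(ann2$cell_type, ann$cell_type[perm_c])
  # all markers equal -> deterministic, recorded tie-break
  v3 <- matrix(1, 20, 3, dimnames = list(NULL, c("INS", "GCG", "SST")))
  expr3 <- expression_matrix(v3, data.frame(cell_id = paste0("c", 1:20)),
                             data.frame(gene_id = colnames(v3)))
  ann3 <- assign_cell_types(rep(1, 20), expr3, markers)
  expect_true(ann3$tie_broken[["1"]])
  expect_equal(unname(ann3$cluster_label[["1"]]), "alpha")  # lexicographic
  # no markers present at all -> error
  expect_error(assign_cell_types(rep(1, 20), expr3,
                                 data.frame(cell_type = "x",
                                            gene_symbol = "ABSENT")),
               "no marker genes")
})

test_that("planted six-type dataset is annotated almost perfectly", {
  cfg <- simulation_config(
    n_genes = 1000, n_cells_per_well = 25,
    type_programs = list(n_genes_per_type = 60, mean = 1.5, sd = 0.5,
                         det_coupling = 0.75))
  x <- prep_expr(cfg)
  emb <- embed_cells(x$expr)
  ann <- resolution_sweep(emb, seed = 1)
  ann <- assign_cell_types(ann, x$expr, default_marker_table(cfg))
  truth <- x$truth$cells$true_type[match(x$expr$cell_meta$cell_id,
                                         x$truth$cells$cell_id)]
  expect_gte(mean(ann$cell_type == truth), 0.95)
})
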
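toy_cm <- function(counts, contamination = 0, mito = 0) {
  n <- nrow(counts)
  g <- ncol(counts)
  cell_meta <- data.frame(cell_id = paste0("c", seq_len(n)),
                          donor = "d1", replicate = "r1", time_h = 1,
                          glucose_arm = "low",
                          contamination_frac = rep_len(contamination, n),
                          mito_frac = rep_len(mito, n))
  gene_meta <- data.frame(gene_id = paste0("g", seq_len(g)),
                          symbol = paste0("g", seq_len(g)),
                          chromosome = "1", is_mito = FALSE, is_ribo = FALSE)
  count_matrix(counts, cell_meta, gene_meta)
}

test_that("contamination filter is a strict > rule at the boundary", {
  counts <- matrix(5, 4, 8)
  cm <- toy_cm(counts, contamination = c(0.11, 0.10, 0.099, 0))
  res <- apply_qc_filters(cm, gene_min_cells = 0, outlier_method = "none")
  expect_setequal(res$cell_meta$cell_id, c("c2", "c3", "c4"))
  rep <- attr(res, "qc_report")
  expect_equal(rep$removed[rep$rule == "contamination"], 1)
})

test_that("filters are a no-op without mito genes or contamination", {
  counts <- matrix(rpois(80, 5) + 1, 10, 8)
  cm <- toy_cm(counts)
  res <- apply_qc_filters(cm, gene_min_cells = 0, outlier_method = "none")
  expect_equal(dim(res$counts), dim(cm$counts))
})

test_that("genes expressed in at most gene_min_cells cells are removed", {
  counts <- matrix(0, 10, 3)
  counts[1:5, 1] <- 1   # exactly 5 cells -> removed (<= 5 rule)
  counts[1:6, 2] <- 1   # 6 cells -> kept
  counts[, 3] <- 1      # keeps cells nonzero
  cm <- toy_cm(counts)
  res <- apply_qc_filters(cm, outlier_method = "none")
  expect_setequal(res$gene_meta$gene_id, c("g2", "g3"))
})

test_that("mito/ribo genes are dropped and all-removed cells error", {
  counts <- matrix(3, 4, 4)
  cm <- toy_cm(counts)
  cm$gene_meta$is_mito[1] <- TRUE
  cm$gene_meta$is_ribo[2] <- TRUE
  res <- apply_qc_filters(cm, gene_min_cells = 0, outlier_method = "none")
  expect_setequal(res$gene_meta$gene_id, c("g3", "g4"))
  expect_error(apply_qc_filters(toy_cm(counts, contamination = 0.5)),
               "all cells removed")
  rep <- attr(res, "qc_report")
  expect_equal(sum(rep$removed[grepl("^gene", rep$rule)]),
               ncol(cm$counts) - ncol(res$counts))
})

test_that("cell filtering is invariant to cell order", {
  cfg <- null_config(n_genes = 200, n_cells_per_well = 10)
  sim <- simulate_dataset(cfg)
  res1 <- apply_qc_filters(sim$matrix)
  perm <- sample(nrow(sim$matrix$counts))
  cm2 <- count_matrix(sim$matrix$counts[perm, ],
                      sim$matrix$cell_meta[perm, ], sim$matrix$gene_meta)
  res2 <- apply_qc_filters(cm2)
  expect_setequal(res1$cell_meta$cell_id, res2$cell_meta$cell_id)
  expect_setequal(res1$gene_meta$gene_id, res2$gene_meta$gene_id)
})

test_that("robust-z and isolation-forest outlier rules flag planted outliers", {
  counts <- matrix(rpois(200 * 50, 20), 200, 50)
  counts[1, ] <- rpois(50, 2000)  # extreme library
  cm <- toy_cm(counts)
  res <- apply_qc_filters(cm, gene_min_cells = 0, outlier_method = "robust_z")
  expect_false("c1" %in% res$cell_meta$cell_id)
  res2 <- apply_qc_filters(cm, gene_min_cells = 0,
                           outlier_method = "isolation_forest",
                           outlier_forest_frac = 0.01, seed = 1)
  expect_false("c1" %in% res2$cell_meta$cell_id)
  res3 <- apply_qc_filters(cm, gene_min_cells = 0,
                           outlier_method = "isolation_forest",
                           outlier_forest_frac = 0.01, seed = 1)
  expect_identical(res2$cell_meta$cell_id, res3$cell_meta$cell_id)
  expect_error(apply_qc_filters(cm, outlier_method = "bogus"))
})

test_that("ln(CP10K+1) normalization matches hand arithmetic", {
  counts <- matrix(0, 2, 4)
  counts[1, ] <- c(1, 0, 7, 9992)       # total 10000
  counts[2, ] <- c(7, 3493, 0, 0)       # total 3500
  cm <- toy_cm(counts)
  expr <- normalize_log_cp10k(cm)
  v <- as.matrix(expr$values)
  expect_equal(v[1, 1], log(2), tolerance = 1e-12)
  expect_equal(v[1, 2], 0)
  expect_equal(v[2, 1], log(21), tolerance = 1e-12)
  # row sums of expm1 equal 10,000
  expect_equal(unname(rowSums(expm1(v))), c(1e4, 1e4), tolerance = 1e-6)
  bad <- toy_cm(matrix(c(1, 0), 2, 1))
  expect_error(normalize_log_cp10k(bad), "zero total")
})

test_that("sex check separates male-like and female-like samples", {
  for (sex in c("male", "female")) {
    sim <- simulate_dataset(null_config(n_genes = 300, n_cells_per_well = 10,
                                        sex = sex))
    rep <- qc_reports(sim$matrix)  # raw matrix keeps XIST/chrY genes
    expect_true(rep$sex_check_available)
    if (sex == "male") expect_true(all(rep$sex_check$ratio < 0.1))
    else expect_true(all(rep$sex_check$ratio > 10))
  }
  # XIST absent -> unavailable, no error
  sim <- simulate_dataset(null_config(n_genes = 300, n_cells_per_well = 5))
  keep <- sim$matrix$gene_meta$symbol != "XIST"
  cm <- count_matrix(sim$matrix$counts[, keep],
                     sim$matrix$cell_meta, sim$matrix$gene_meta[keep, ])
  rep2 <- qc_reports(cm)
  expect_false(rep2$sex_check_available)
  expect_null(rep2$sex_check)
})

test_that("replicate pseudobulk correlation behaves at both extremes", {
  sim <- simulate_dataset(null_config(n_genes = 2200, n_cells_per_well = 20))
  cm <- sim$matrix
  labels <- rep("beta", nrow(cm$counts))
  rep <- qc_reports(cm, annotation = labels)
  expect_true(all(rep$replicate_correlation$pearson_r > 0.85))
  # identical replicate pseudobulks give r = 1 exactly
  cm2 <- cm
  r1 <- cm$cell_meta$replicate == "rep1"
  idx1 <- which(r1)[1:10]
  idx2 <- which(!r1)[1:10]
  sub <- count_matrix(rbind(cm$counts[idx1, ], cm$counts[idx1, ]),
                      rbind(cm$cell_meta[idx1, ], cm$cell_meta[idx2, ]),
                      cm$gene_meta)
  rep2 <- qc_reports(sub, annotation = rep("beta", 20))
  expect_true(all(abs(rep2$replicate_correlation$pearson_r - 1) < 1e-12))
  # independent random pseudobulks: |r| small (null permutation scale)
  set.seed(1)
  g <- 2000
  ca <- matrix(rpois(g * 10, 5), 10, g)
  cb <- matrix(rpois(g * 10, 5), 10, g)
  pa <- colSums(ca) / sum(ca)
  pb <- colSums(cb) / sum(cb)
  null_r <- replicate(200, cor(pa, sample(pb)))
  cmx <- toy_cm(rbind(ca, cb))
  cmx$cell_meta$replicate <- rep(c("r1", "r2"), each = 10)
  rep3 <- qc_reports(cmx, annotation = rep("beta", 20))
  expect_lt(abs(rep3$replicate_correlation$pearson_r),
            max(abs(null_r)) + 3 * sd(null_r))
})
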
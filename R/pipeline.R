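#' Run the full analysis pipeline on a simulated dataset
#'
#' End-to-end driver: simulate counts, apply QC filters, normalize to
#' ln(CP10K+1), embed and annotate cell types, compute standardized
#' interpolated time per cell type x glucose arm, run the discrete (BvH,
#' BvL, LvH at each time point) and continuous (time, glucose,
#' time:glucose) hurdle designs per cell type, discover consensus
#' co-expression modules, test them for effector-gene enrichment, and score
#' candidate genes against simulated association scores derived from the
#' planted truth. Fully deterministic given `config` (which carries the
#' simulation seed) and `seed` (analysis randomness).
#'
#' @param config a [simulation_config()].
#' @param seed analysis seed (clustering, splits, permutations).
#' @param min_cells_per_type cell types with fewer cells are skipped for
#'   differential expression (mirrors removal of rare types).
#' @param dge_time_points time points for discrete designs (defaults to all
#'   non-zero sampled points).
#' @param module_max_genes cap on genes entering module discovery per cell
#'   type.
#' @param module_min_genes skip module discovery for cell types with fewer
#'   selected genes.
#' @param module_n_iter DPGP sweeps per run.
#' @param module_cell_types restrict module discovery to these annotated
#'   types (NULL = all eligible).
#' @param n_perm permutations for priority scoring.
#' @param interp_n,interp_w interpolation parameters.
#' @param run_prioritization,run_modules stage switches.
#' @return list with `qc` (filtered counts + report), `expr`, `annotation`,
#'   `interpolated` (per-cell data.frame), `dge` (named list of results),
#'   `modules`, `enrichment`, `priority`, `truth`.
#' @export
run_pipeline <- function(config = simulation_config(), seed = 1,
                         min_cells_per_type = 80,
                         dge_time_points = NULL,
                         module_max_genes = 120, module_min_genes = 30,
                         module_n_iter = 60, module_cell_types = NULL,
                         n_perm = 1000,
                         interp_n = 75, interp_w = 0.25,
                         run_prioritization = TRUE, run_modules = TRUE) {
  sim <- simulate_dataset(config)
  qc <- apply_qc_filters(sim$matrix, seed = seed)
  expr <- normalize_log_cp10k(qc)
  emb <- embed_cells(expr)
  ann <- resolution_sweep(emb, seed = seed)
  ann <- assign_cell_types(ann, expr, default_marker_table(config))
  labels <- ann$cell_type

  meta <- expr$cell_meta
  n_cells <- nrow(meta)
  that_std <- rep(NA_real_, n_cells)
  interp_rows <- data.frame(cell_id = meta$cell_id, cell_type = labels,
                            t_sampled = meta$time_h,
                            t_hat_raw = NA_real_, t_hat_std = NA_real_)
  post <- which(meta$time_h > 0)
  for (ty in unique(labels)) {
    for (a in c("low", "high")) {
      idx <- post[labels[post] == ty & meta$glucose_arm[post] == a]
      if (length(idx) < 5) next
      sub <- expression_matrix(expr$values[idx, , drop = FALSE],
                               meta[idx, , drop = FALSE], expr$gene_meta)
      n_use <- min(interp_n, length(idx) - 1L)
      it <- interpolate_time(sub, meta$time_h[idx], n = n_use, w = interp_w)
      std <- standardize_time(it$t_hat_raw)
      that_std[idx] <- std
      interp_rows$t_hat_raw[idx] <- it$t_hat_raw
      interp_rows$t_hat_std[idx] <- std
    }
  }

  types <- names(which(table(labels) >= min_cells_per_type))
  if (is.null(dge_time_points))
    dge_time_points <- setdiff(sort(unique(meta$time_h)), 0)
  dge <- list()
  for (ty in types) {
    for (tp in dge_time_points) {
      for (dn in c("BvH", "BvL", "LvH")) {
        key <- paste(ty, dn, tp, sep = "_")
        dge[[key]] <- tryCatch(
          run_design(expr, hurdle_design(dn, tp), cell_type = ty,
                     labels = labels),
          error = function(e) NULL)
      }
    }
    for (dn in c("time", "glucose", "time_glucose")) {
      key <- paste(ty, dn, sep = "_")
      dge[[key]] <- tryCatch(
        run_design(expr, hurdle_design(dn), cell_type = ty,
                   labels = labels, that_std = that_std),
        error = function(e) NULL)
    }
  }
  dge <- dge[!vapply(dge, is.null, TRUE)]

  modules <- list()
  enrichment <- list()
  if (run_modules) {
    mod_types <- module_cell_types %||% types
    effectors <- sim$truth$genes$gene_id[sim$truth$genes$is_effector]
    for (ty in intersect(mod_types, types)) {
      d_ty <- dge[grepl(paste0("^", ty, "_"), names(dge))]
      sel <- tryCatch(select_module_genes(d_ty), warning = function(w)
        character(0), error = function(e) character(0))
      if (length(sel) < module_min_genes) next
      idx <- which(labels == ty & meta$time_h > 0 & !is.na(that_std))
      sub <- expression_matrix(expr$values[idx, , drop = FALSE],
                               meta[idx, , drop = FALSE], expr$gene_meta)
      ms <- tryCatch(
        discover_modules(sub, that_std[idx], meta$glucose_arm[idx], d_ty,
                         max_genes = module_max_genes,
                         n_iter = module_n_iter, seed = seed),
        error = function(e) NULL)
      if (is.null(ms)) next
      modules[[ty]] <- ms
      if (length(ms$modules) > 0) {
        enrichment[[ty]] <- enrich_modules(
          ms, list(effector = effectors),
          universe = unique(unlist(lapply(d_ty, `[[`, "gene"))))
      }
    }
  }

  priority <- NULL
  features <- NULL
  if (run_prioritization) {
    features <- build_feature_matrix(expr, ann, dge, embedding = emb)
    scores <- simulate_gene_scores(sim$truth, rownames(features$features),
                                   seed = seed)
    priority <- pops_prioritize(features, scores, n_perm = n_perm,
                                seed = seed)
  }

  list(qc = qc, qc_report = attr(qc, "qc_report"), expr = expr,
       annotation = ann, interpolated = interp_rows, dge = dge,
       modules = modules, enrichment = enrichment, features = features,
       priority = priority, truth = sim$truth)
}

#' Simulated gene-level association scores
#'
#' Stand-in for gene-level GWAS association z-scores: effector genes draw
#' from a shifted normal, all others from a standard normal.
#'
#' @param truth ground-truth list from [simulate_dataset()].
#' @param genes gene ids to score.
#' @param effector_shift mean shift for effector genes.
#' @param seed RNG seed.
#' @return data.frame with `gene_id`, `score`.
#' @export
simulate_gene_scores <- function(truth, genes, effector_shift = 2,
                                 seed = 1) {
  eff <- genes %in% truth$genes$gene_id[truth$genes$is_effector]
  with_seed(seed, data.frame(
    gene_id = genes,
    score = rnorm(length(genes)) + effector_shift * eff,
    stringsAsFactors = FALSE))
}
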
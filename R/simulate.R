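#' Configuration for the islet time-course simulator
#'
#' Builds the full parameter set for [simulate_dataset()]. Defaults emulate
#' the study design of a 24-hour glucose-exposure experiment: two donors with
#' two replicate wells each, sampling at 0, 1, 2, 4, 8, 12 and 24 hours, a
#' low (2.8 mM) and a high (15 mM) glucose arm with no high-glucose wells at
#' 0 h, and six islet cell types with canonical marker genes (GCG alpha, INS
#' beta, SST delta, PPY gamma, PRSS1 acinar, KRT19 ductal).
#'
#' Expression follows a two-part process per gene and cell: a Bernoulli
#' detection step whose logit depends on the gene, sequencing depth and
#' (attenuated) the planted effects, and, when detected, a count drawn from a
#' negative binomial (default) or rounded log-normal whose log-mean carries
#' the planted time, glucose and time:glucose terms evaluated at the cell's
#' phase-offset time. Phase offsets instantiate response asynchrony: each
#' cell's effective time is a truncated-normal jitter around its sampled
#' time.
#'
#' @param n_donors,n_replicates_per_donor wells are formed per donor x
#'   replicate x time x arm.
#' @param time_points_h sampled time points in hours; must include 0 if basal
#'   cells are wanted.
#' @param cell_types data.frame with columns `name`, `proportion`, `marker`
#'   (marker gene symbol). Proportions must sum to 1.
#' @param n_genes total gene count including markers and housekeeping
#'   (sex-check, mitochondrial, ribosomal) genes.
#' @param n_cells_per_well cells sampled per well.
#' @param effects list: `n_time`, `n_glucose`, `n_interaction` planted gene
#'   counts and `time_mag`, `glucose_mag`, `interaction_mag` log-scale
#'   magnitudes (effect at 24 h / in the high arm), plus `mixed_signs`
#'   (logical; random sign per gene).
#' @param modules list: `n_modules`, `size`, `magnitude`, and `shapes`
#'   (character vector recycled over modules; see Details).
#' @param type_programs list: `n_genes_per_type` background genes per cell
#'   type carrying a type-specific log-expression loading drawn from
#'   N(`mean`, `sd`), with `det_coupling` of the loading applied to the
#'   detection logit. These programs give each cell type a broad
#'   transcriptomic identity beyond its single canonical marker, as in real
#'   tissue.
#' @param hurdle list: `mean_logit`, `sd_logit` for gene detection
#'   intercepts, `depth_coef` (detection dependence on log depth), and
#'   `effect_coupling` (fraction of the log-mean effect also applied to the
#'   detection logit).
#' @param expressed_dist `"nb"` or `"lognormal"` for the expressed-component
#'   count distribution.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters for the
#'   per-gene NB dispersion (phi; variance = mu + phi mu^2).
#' @param lognormal_sd sd of log counts in `"lognormal"` mode.
#' @param depth list: `meanlog`, `sdlog` for the per-cell depth factor.
#' @param base_meanlog,base_sdlog normal parameters for gene baseline
#'   log-mean expression.
#' @param phase_sd_h sd (hours) of the truncated-normal phase offset.
#' @param mito_frac_shape1,mito_frac_shape2 Beta parameters for the per-cell
#'   mitochondrial fraction metadata; a `mito_high_frac` share of cells is
#'   drawn from Beta(20, 8) to emulate dying cells.
#' @param contamination_shape1,contamination_shape2 Beta parameters for the
#'   ambient-contamination fraction metadata.
#' @param doublet_rate Bernoulli rate for the ground-truth doublet flag
#'   (metadata only; no transcript mixing is simulated).
#' @param effector_module_frac,effector_background_frac fraction of
#'   module-1 genes / of remaining genes labeled as effector genes.
#' @param sex `"male"` (XIST silent, chrY expressed) or `"female"`.
#' @param marker_mag log-scale marker boost within the marker's cell type.
#' @param seed integer seed; identical config + seed reproduces the dataset
#'   bit-identically.
#'
#' @details Module shapes available: `"time_up"` (linear rise with time in
#'   both arms; genes flagged as time effects), `"glucose_step"` (constant
#'   shift in the high arm; glucose flag), `"late_divergence"` (high-arm-only
#'   rise after 12 h; interaction flag). Module genes draw their entire
#'   planted effect from the module profile so flags and profiles agree.
#'
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(
    n_donors = 2,
    n_replicates_per_donor = 2,
    time_points_h = c(0, 1, 2, 4, 8, 12, 24),
    cell_types = data.frame(
      name = c("alpha", "beta", "delta", "gamma", "acinar", "ductal"),
      proportion = c(0.30, 0.30, 0.05, 0.03, 0.20, 0.12),
      marker = c("GCG", "INS", "SST", "PPY", "PRSS1", "KRT19"),
      stringsAsFactors = FALSE),
    n_genes = 2000,
    n_cells_per_well = 100,
    effects = list(n_time = 50, n_glucose = 50, n_interaction = 50,
                   time_mag = 1.0, glucose_mag = 1.0, interaction_mag = 1.5,
                   mixed_signs = TRUE),
    modules = list(n_modules = 3, size = 20, magnitude = 1.5,
                   shapes = c("time_up", "glucose_step", "late_divergence")),
    type_programs = list(n_genes_per_type = 120, mean = 1.5, sd = 0.5,
                         det_coupling = 0.75),
    hurdle = list(mean_logit = 0.8, sd_logit = 0.8, depth_coef = 0.5,
                  effect_coupling = 0.5),
    expressed_dist = c("nb", "lognormal"),
    dispersion_meanlog = log(0.3), dispersion_sdlog = 0.5,
    lognormal_sd = 0.35,
    depth = list(meanlog = 0, sdlog = 0.35),
    base_meanlog = 0, base_sdlog = 1,
    phase_sd_h = 1.5,
    mito_frac_shape1 = 2, mito_frac_shape2 = 28, mito_high_frac = 0.02,
    contamination_shape1 = 1.5, contamination_shape2 = 30,
    doublet_rate = 0.03,
    effector_module_frac = 0.6, effector_background_frac = 0.05,
    sex = c("male", "female"),
    marker_mag = 4,
    seed = 1) {
  expressed_dist <- match.arg(expressed_dist)
  sex <- match.arg(sex)
  cfg <- list(
    n_donors = n_donors, n_replicates_per_donor = n_replicates_per_donor,
    time_points_h = sort(unique(time_points_h)), cell_types = cell_types,
    n_genes = n_genes, n_cells_per_well = n_cells_per_well,
    effects = effects, modules = modules, type_programs = type_programs,
    hurdle = hurdle,
    expressed_dist = expressed_dist,
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    lognormal_sd = lognormal_sd, depth = depth,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    phase_sd_h = phase_sd_h,
    mito_frac_shape1 = mito_frac_shape1, mito_frac_shape2 = mito_frac_shape2,
    mito_high_frac = mito_high_frac,
    contamination_shape1 = contamination_shape1,
    contamination_shape2 = contamination_shape2,
    doublet_rate = doublet_rate,
    effector_module_frac = effector_module_frac,
    effector_background_frac = effector_background_frac,
    sex = sex, marker_mag = marker_mag, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 0 || cfg$n_cells_per_well <= 0 ||
      cfg$n_donors <= 0 || cfg$n_replicates_per_donor <= 0)
    stop("config must specify positive cell, gene, donor and replicate counts")
  if (abs(sum(cfg$cell_types$proportion) - 1) > 1e-8)
    stop("cell type proportions must sum to 1")
  mags <- unlist(cfg$effects[c("time_mag", "glucose_mag", "interaction_mag")])
  if (!all(is.finite(mags))) stop("effect magnitudes must be finite")
  n_special <- nrow(cfg$cell_types) + 4 + 10 + 10  # markers, sex, mito, ribo
  n_eff <- cfg$effects$n_time + cfg$effects$n_glucose + cfg$effects$n_interaction
  n_mod <- if (cfg$modules$n_modules > 0) cfg$modules$n_modules * cfg$modules$size else 0
  n_prog <- cfg$type_programs$n_genes_per_type * nrow(cfg$cell_types)
  if (cfg$n_genes < n_special + n_eff + n_mod + n_prog)
    stop("n_genes too small for the requested special, effect, module and program genes")
  invisible(cfg)
}

# Module temporal profile on log-expression scale.
# s = effective time scaled to [0,1]; h = 1 in the high-glucose arm.
module_shape_value <- function(shape, s, h, mag) {
  switch(shape,
    time_up = mag * s,
    glucose_step = mag * h,
    late_divergence = mag * pmax(0, (s - 0.5) * 2) * h,
    stop("unknown module shape: ", shape))
}

module_shape_flag <- function(shape) {
  switch(shape, time_up = "time", glucose_step = "glucose",
         late_divergence = "interaction")
}

build_gene_table <- function(cfg) {
  markers <- cfg$cell_types$marker
  sexg <- c("XIST", "RPS4Y1", "DDX3Y", "EIF1AY")
  mito <- paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND5", "CO1", "CO2",
                          "CO3", "ATP6", "CYB"))
  ribo <- c(paste0("RPS", c(2, 3, 4, 6, 8)), paste0("RPL", c(3, 4, 5, 7, 8)))
  special <- c(markers, sexg, mito, ribo)
  n_bg <- cfg$n_genes - length(special)
  bg <- sprintf("GENE%04d", seq_len(n_bg))
  gene_id <- c(special, bg)
  chrom <- c(sample(as.character(1:22), length(markers), replace = TRUE),
             c("X", "Y", "Y", "Y"), rep("MT", length(mito)),
             sample(as.character(1:22), length(ribo), replace = TRUE),
             sample(as.character(1:22), n_bg, replace = TRUE))
  g <- data.frame(
    gene_id = gene_id, symbol = gene_id, chromosome = chrom,
    is_mito = grepl("^MT-", gene_id),
    is_ribo = grepl("^RP[SL]", gene_id) & !grepl("^RPS4Y", gene_id),
    stringsAsFactors = FALSE)
  g$base_log_mean <- rnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog)
  g$det_logit <- rnorm(cfg$n_genes, cfg$hurdle$mean_logit, cfg$hurdle$sd_logit)
  g$phi <- exp(rnorm(cfg$n_genes, cfg$dispersion_meanlog, cfg$dispersion_sdlog))
  g$marker_type <- NA_character_
  g$marker_type[match(markers, g$gene_id)] <- cfg$cell_types$name
  # housekeeping expression levels; XIST/chrY encode the configured sex
  xist_on <- cfg$sex == "female"
  g$det_logit[g$gene_id == "XIST"] <- if (xist_on) 2 else -12
  g$det_logit[g$chromosome == "Y"] <- if (xist_on) -12 else 1.5
  g$det_logit[g$is_mito | g$is_ribo] <- 2.5
  g$base_log_mean[g$is_mito | g$is_ribo] <- 1.5

  # planted single-gene effects on background genes
  g$beta_time <- g$beta_glucose <- g$beta_interaction <- 0
  g$module <- NA_integer_
  g$module_shape <- NA_character_
  bg_idx <- which(g$gene_id %in% bg)
  take <- function(pool, n) pool[seq_len(n)]
  eff <- cfg$effects
  cursor <- bg_idx
  sgn <- function(n) if (isTRUE(eff$mixed_signs)) sample(c(-1, 1), n, TRUE) else rep(1, n)
  if (eff$n_time > 0) {
    i <- take(cursor, eff$n_time); cursor <- setdiff(cursor, i)
    g$beta_time[i] <- eff$time_mag * sgn(length(i))
  }
  if (eff$n_glucose > 0) {
    i <- take(cursor, eff$n_glucose); cursor <- setdiff(cursor, i)
    g$beta_glucose[i] <- eff$glucose_mag * sgn(length(i))
  }
  if (eff$n_interaction > 0) {
    i <- take(cursor, eff$n_interaction); cursor <- setdiff(cursor, i)
    g$beta_interaction[i] <- eff$interaction_mag * sgn(length(i))
  }
  mod <- cfg$modules
  if (mod$n_modules > 0) {
    shapes <- rep(mod$shapes, length.out = mod$n_modules)
    for (m in seq_len(mod$n_modules)) {
      i <- take(cursor, mod$size); cursor <- setdiff(cursor, i)
      g$module[i] <- m
      g$module_shape[i] <- shapes[m]
      flag <- module_shape_flag(shapes[m])
      if (flag == "time") g$beta_time[i] <- mod$magnitude
      if (flag == "glucose") g$beta_glucose[i] <- mod$magnitude
      if (flag == "interaction") g$beta_interaction[i] <- mod$magnitude
    }
  }
  # type-program loadings: broad per-type identity genes
  tp <- cfg$type_programs
  n_types <- nrow(cfg$cell_types)
  W <- matrix(0, nrow(g), n_types,
              dimnames = list(g$gene_id, cfg$cell_types$name))
  if (tp$n_genes_per_type > 0) {
    for (ty in seq_len(n_types)) {
      i <- take(cursor, tp$n_genes_per_type); cursor <- setdiff(cursor, i)
      W[i, ty] <- rnorm(length(i), tp$mean, tp$sd)
    }
  }
  attr(g, "type_loadings") <- W
  # planted-effect and module genes are drawn among well-expressed genes so
  # that recovery is a property of the method, not of the prefilter
  planted <- g$beta_time != 0 | g$beta_glucose != 0 |
    g$beta_interaction != 0 | !is.na(g$module)
  g$det_logit[planted] <- pmax(g$det_logit[planted], 1.2)
  g$base_log_mean[planted] <- pmax(g$base_log_mean[planted], 0.5)
  g$is_time <- g$beta_time != 0
  g$is_glucose <- g$beta_glucose != 0
  g$is_interaction <- g$beta_interaction != 0
  # effector labels: enrich module 1 (if any), sparse background
  g$is_effector <- FALSE
  m1 <- which(!is.na(g$module) & g$module == 1)
  if (length(m1) > 0) {
    n_eff1 <- round(cfg$effector_module_frac * length(m1))
    g$is_effector[sample(m1, n_eff1)] <- TRUE
  }
  rest <- setdiff(seq_len(nrow(g)), m1)
  n_bg_eff <- round(cfg$effector_background_frac * length(rest))
  g$is_effector[sample(rest, n_bg_eff)] <- TRUE
  g
}

build_cell_table <- function(cfg) {
  wells <- expand.grid(
    donor = paste0("donor", seq_len(cfg$n_donors)),
    replicate = paste0("rep", seq_len(cfg$n_replicates_per_donor)),
    time_h = cfg$time_points_h,
    glucose_arm = c("low", "high"),
    stringsAsFactors = FALSE)
  wells <- wells[!(wells$time_h == 0 & wells$glucose_arm == "high"), ]
  wells <- wells[order(wells$donor, wells$replicate, wells$time_h,
                       wells$glucose_arm), ]
  n <- nrow(wells) * cfg$n_cells_per_well
  cells <- wells[rep(seq_len(nrow(wells)), each = cfg$n_cells_per_well), ]
  rownames(cells) <- NULL
  cells$cell_id <- sprintf("CELL%06d", seq_len(n))
  cells$true_type <- sample(cfg$cell_types$name, n, replace = TRUE,
                            prob = cfg$cell_types$proportion)
  # truncated-normal phase offset around the sampled time (response asynchrony)
  te <- rnorm(n, cells$time_h, cfg$phase_sd_h)
  bad <- which(te < 0 | te > max(cfg$time_points_h))
  while (length(bad) > 0) {
    te[bad] <- rnorm(length(bad), cells$time_h[bad], cfg$phase_sd_h)
    bad <- bad[te[bad] < 0 | te[bad] > max(cfg$time_points_h)]
  }
  te[cells$time_h == 0] <- 0
  cells$te <- te
  cells$depth_factor <- exp(rnorm(n, cfg$depth$meanlog, cfg$depth$sdlog))
  hi <- runif(n) < cfg$mito_high_frac
  cells$mito_frac <- ifelse(hi,
    stats::rbeta(n, 20, 8),
    stats::rbeta(n, cfg$mito_frac_shape1, cfg$mito_frac_shape2))
  cells$contamination_frac <- stats::rbeta(n, cfg$contamination_shape1,
                                           cfg$contamination_shape2)
  cells$is_doublet <- runif(n) < cfg$doublet_rate
  cells
}

#' Simulate an islet glucose time-course scRNA-seq dataset
#'
#' Draws a cell x gene integer count matrix plus full ground truth from a
#' [simulation_config()]. See that help page for the generative model.
#'
#' @param config a `sim_config` object.
#' @return A list with elements `matrix` (a [count_matrix]) and `truth`
#'   (list with `genes` and `cells` data.frames giving the planted effect
#'   flags, module memberships, effector labels, per-cell true type and
#'   phase-offset effective time).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    genes <- build_gene_table(config)
    cells <- build_cell_table(config)
    G <- nrow(genes); N <- nrow(cells)
    tmax <- max(config$time_points_h)
    s <- cells$te / tmax
    h <- as.numeric(cells$glucose_arm == "high")
    logdepth <- log(cells$depth_factor)
    type_idx <- match(cells$true_type, config$cell_types$name)

    # per-gene x per-cell effect term on the log-mean scale
    # (chunked over cells to bound memory)
    coupling <- config$hurdle$effect_coupling
    trip_i <- vector("list", 0); trip_j <- vector("list", 0)
    trip_x <- vector("list", 0)
    marker_row <- match(config$cell_types$marker, genes$gene_id)
    chunk_size <- 512L
    starts <- seq(1L, N, by = chunk_size)
    k <- 0L
    for (st in starts) {
      idx <- st:min(st + chunk_size - 1L, N)
      nc <- length(idx)
      eta <- outer(genes$beta_time, s[idx]) +
        outer(genes$beta_glucose, h[idx]) +
        outer(genes$beta_interaction, s[idx] * h[idx])
      W <- attr(genes, "type_loadings")
      prog <- W[, type_idx[idx], drop = FALSE]
      modg <- which(!is.na(genes$module))
      if (length(modg) > 0) {
        # module genes: replace the linear encoding with the shape profile
        for (gi in modg) {
          eta[gi, ] <- module_shape_value(genes$module_shape[gi], s[idx],
                                          h[idx], abs_mag(genes, gi, config))
        }
      }
      # marker structure: strong in-type expression, suppressed elsewhere
      det_logit <- matrix(genes$det_logit, G, nc) +
        coupling * eta +
        config$type_programs$det_coupling * prog +
        config$hurdle$depth_coef *
          matrix(logdepth[idx], G, nc, byrow = TRUE)
      mu_log <- matrix(genes$base_log_mean, G, nc) + eta + prog +
        matrix(logdepth[idx], G, nc, byrow = TRUE)
      for (ct in seq_along(marker_row)) {
        gi <- marker_row[ct]
        in_type <- type_idx[idx] == ct
        det_logit[gi, ] <- ifelse(in_type, 4, -4)
        mu_log[gi, in_type] <- mu_log[gi, in_type] + config$marker_mag
      }
      z <- matrix(runif(G * nc), G, nc) < plogis(det_logit)
      nz <- which(z)
      mu <- exp(mu_log[nz])
      if (config$expressed_dist == "nb") {
        size <- 1 / matrix(genes$phi, G, nc)[nz]
        cts <- 1 + rnbinom(length(nz), mu = mu, size = size)
      } else {
        cts <- pmax(1, round(exp(rnorm(length(nz), log(mu),
                                       config$lognormal_sd))))
      }
      k <- k + 1L
      trip_i[[k]] <- ((nz - 1L) %% G) + 1L            # gene index
      trip_j[[k]] <- idx[((nz - 1L) %/% G) + 1L]       # cell index
      trip_x[[k]] <- cts
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(trip_j), j = unlist(trip_i), x = unlist(trip_x),
      dims = c(N, G), dimnames = list(cells$cell_id, genes$gene_id))

    cell_meta <- cells[, c("cell_id", "donor", "replicate", "time_h",
                           "glucose_arm", "contamination_frac", "mito_frac")]
    gene_meta <- genes[, c("gene_id", "symbol", "chromosome", "is_mito",
                           "is_ribo")]
    cm <- count_matrix(counts, cell_meta, gene_meta)
    truth <- list(genes = genes, cells = cells)
    list(matrix = cm, truth = truth)
  })
}

# magnitude actually planted for a module gene (module magnitude, signed +)
abs_mag <- function(genes, gi, config) {
  config$modules$magnitude
}

#' Marker table for the default simulated cell types
#'
#' @param config a `sim_config`; defaults to [simulation_config()].
#' @return data.frame with columns `cell_type`, `gene_symbol` suitable for
#'   [assign_cell_types()].
#' @export
default_marker_table <- function(config = simulation_config()) {
  data.frame(cell_type = config$cell_types$name,
             gene_symbol = config$cell_types$marker,
             stringsAsFactors = FALSE)
}
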
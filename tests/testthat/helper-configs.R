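# Shared simulation configurations for the test suite. Sizes are kept small
# for unit tests; acceptance tests build their own study-scale configs.

one_type <- function() data.frame(name = "beta", proportion = 1,
                                  marker = "INS", stringsAsFactors = FALSE)

no_effects <- function(mag = 0)
  list(n_time = 0, n_glucose = 0, n_interaction = 0,
       time_mag = mag, glucose_mag = mag, interaction_mag = mag,
       mixed_signs = TRUE)

no_modules <- function()
  list(n_modules = 0, size = 0, magnitude = 0, shapes = "time_up")

no_programs <- function()
  list(n_genes_per_type = 0, mean = 0, sd = 0, det_coupling = 0)

# single-cell-type null dataset (no planted structure)
null_config <- function(n_genes = 400, n_cells_per_well = 20, seed = 1, ...)
  simulation_config(n_genes = n_genes, n_cells_per_well = n_cells_per_well,
                    cell_types = one_type(), effects = no_effects(),
                    modules = no_modules(), type_programs = no_programs(),
                    seed = seed, ...)

# single-cell-type dataset with one planted effect class
effect_config <- function(kind = c("time", "glucose", "interaction"),
                          n = 20, mag = 1, n_genes = 600,
                          n_cells_per_well = 30, seed = 1, ...) {
  kind <- match.arg(kind)
  eff <- no_effects()
  eff[[paste0("n_", if (kind == "interaction") "interaction" else kind)]] <- n
  eff[[paste0(kind, "_mag")]] <- mag
  simulation_config(n_genes = n_genes, n_cells_per_well = n_cells_per_well,
                    cell_types = one_type(), effects = eff,
                    modules = no_modules(), type_programs = no_programs(),
                    seed = seed, ...)
}

# standardized interpolated time proxy from sampled times (for DGE tests
# that do not exercise the interpolation module)
sampled_time_std <- function(meta) {
  that <- rep(NA_real_, nrow(meta))
  for (a in c("low", "high")) {
    i <- which(meta$time_h > 0 & meta$glucose_arm == a)
    if (length(i) > 0) that[i] <- standardize_time(meta$time_h[i])
  }
  that
}

# simulate + QC + normalize in one step
prep_expr <- function(cfg) {
  sim <- simulate_dataset(cfg)
  qc <- apply_qc_filters(sim$matrix)
  list(expr = normalize_log_cp10k(qc), truth = sim$truth, qc = qc)
}

# adjusted Rand index by direct contingency computation (test-side oracle)
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
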
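# glucodyn

Analysis pipeline for single-cell RNA-seq time courses of human pancreatic
islets exposed to low (2.8 mM) and high (15 mM) glucose over 24 hours.
Sustained hyperglycemia remodels islet gene expression, but in a time-course
experiment the effect of glucose is entangled with the effect of time in
culture; `glucodyn` is built for analysts who need to separate the two —
and their interaction — at single-cell-type resolution, and to carry the
results forward into co-expression modules and candidate-gene
prioritization. Because no public dataset is required, the package ships a
seeded synthetic-data generator that emulates the study design (2 donors x
2 replicates x 7 time points x 2 glucose arms x 6 islet cell types with
canonical markers) with planted effects, so every stage is validated
against known ground truth.

## What the package computes

* **QC and normalization** — contamination (>10%), mitochondrial (>50%),
  and UMI-outlier cell filters; low-prevalence and mito/ribo gene removal;
  ln(CP10K+1) normalization; sex-check and replicate-concordance reports.
* **Cell-type annotation** — variable-gene PCA with knee-selected
  components, Leiden clustering across a resolution sweep validated by a
  held-out classifier (largest resolution with minimum per-cluster
  MCC > 0.75), then marker-based labeling.
* **Interpolated time** — per cell, within cell type x glucose arm:
  `t_hat = t*w + [Σ d_i⁻¹ t_i / Σ d_i⁻¹](1−w)` over its `n`
  expression-space nearest neighbors (defaults n = 75, w = 0.25), then
  0–1 standardization; recovers response phase better than sampled time.
* **Hurdle differential expression** — the two-part model
  `logit P(Z=1|X) = Xβ` (detection) and `Y|Z=1 ~ N(Xβ′, σ²)` (level on
  ln(CP10K+1)), tested by the summed-χ² likelihood-ratio statistic across
  both parts. Discrete designs BvH, BvL, LvH at each time point; continuous
  time, glucose and time:glucose designs on interpolated time; covariates
  cell complexity and donor; median-CP10K ≥ 1 prefilter; BH FDR per
  (cell type, design).
* **Module discovery** — loess-smoothed expression over interpolated time
  per glucose arm on a 21-point grid, clustered by a Dirichlet-process
  Gaussian-process mixture (Gibbs sampler, squared-exponential kernel)
  across 45 parameter configurations; consensus co-clustering matrix;
  iterative k-means extraction of modules with within-module co-clustering
  ≥ 0.75 and ≥ 5 genes.
* **Enrichment and prioritization** — upper-tail hypergeometric module
  enrichment against gene-set collections (GMT); a gene x feature matrix
  (PC loadings, Welch marker statistics, mean expression, specificity,
  DGE statistics) fed to a GCV-ridge priority-score model with a pooled
  permutation null, empirical p = (r+1)/(n+1), BH across genes.

## Worked example

```r
library(glucodyn)

cfg  <- simulation_config(n_genes = 1000, n_cells_per_well = 40, seed = 1)
sim  <- simulate_dataset(cfg)
sim$matrix
#> <count_matrix> 2080 cells x 1000 genes
#>   donors: donor1, donor2 | time points (h): 0, 1, 2, 4, 8, 12, 24

qc   <- apply_qc_filters(sim$matrix)
attr(qc, "qc_report")
#>                  rule removed
#> 1       contamination     207
#> 2       mito_fraction      40
#> 3         umi_outlier       1
#> 4 gene_low_prevalence       1
#> 5      gene_mito_ribo      20

expr <- normalize_log_cp10k(qc)
emb  <- embed_cells(expr)
ann  <- resolution_sweep(emb, seed = 1)
ann  <- assign_cell_types(ann, expr, default_marker_table(cfg))
table(ann$cell_type)
#> acinar  alpha   beta  delta ductal  gamma
#>    373    530    576     86    216     51

lvh <- run_design(expr, hurdle_design("LvH", 24),
                  cell_type = "beta", labels = ann$cell_type)
head(lvh[order(lvh$p), c("gene", "coef_cont", "chisq", "df", "p", "q")], 5)
#>         gene coef_cont chisq df        p        q
#> 121 GENE0117     -1.29  94.3  2 3.41e-21 2.97e-18
#> 203 GENE0199      1.21  86.2  2 1.90e-19 8.27e-17
#> 145 GENE0141      1.01  78.1  2 1.13e-17 3.26e-15
#> 143 GENE0139     -1.08  76.1  2 3.02e-17 6.56e-15
#> 177 GENE0173      1.24  75.3  2 4.51e-17 7.84e-15
```

The LvH contrast at 24 h compares beta cells kept in low glucose with beta
cells in high glucose at the same time point, so time in culture is
controlled: 191 of 869 tested genes pass FDR < 5%, and 72% of those hits
carry a planted glucose or time:glucose effect (`sim$truth$genes` holds
the ground truth). `coef_cont` is the high-vs-low shift of the continuous
(expression-level) part on the ln(CP10K+1) scale; `chisq`/`df`/`p` are the
summed two-part likelihood-ratio test.

`run_pipeline(simulation_config(), seed = 1)` runs the whole path —
QC, annotation, interpolated time, all six designs per cell type, consensus
modules, effector enrichment and priority scoring — on the full 5,200-cell
x 2,000-gene design, deterministically.

## Vignette

`vignettes/glucodyn-methods.Rmd` documents the generative model, the
statistical methods, every tunable that matters (with defaults and
rationale), the numerical choices, and the limits of what the synthetic
validation shows about real data.
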
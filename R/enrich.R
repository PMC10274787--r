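#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing `k` overlap
#' genes between a module of size m and a gene set of size K inside a
#' universe of size N (`phyper` with `lower.tail = FALSE` at k - 1). In
#' GO mode, tests with overlap k <= 1 are suppressed (returned as NA).
#'
#' @param module_genes character vector of module gene ids.
#' @param set_genes character vector of gene-set ids (restricted to the
#'   universe before testing).
#' @param universe character vector of background gene ids; the module must
#'   be contained in it.
#' @param go_mode drop one-gene overlaps (default FALSE).
#' @return list with `k`, `K`, `m`, `N`, `p`, `overlap_genes` (`p` is NA
#'   when `go_mode` and k <= 1).
#' @export
overrepresentation_test <- function(module_genes, set_genes, universe,
                                    go_mode = FALSE) {
  if (length(module_genes) == 0) stop("empty module")
  if (!all(module_genes %in% universe))
    stop("module contains genes outside the universe")
  set_in <- intersect(set_genes, universe)
  if (length(set_in) == 0) stop("gene set does not intersect the universe")
  N <- length(unique(universe))
  K <- length(set_in)
  m <- length(unique(module_genes))
  ov <- intersect(module_genes, set_in)
  k <- length(ov)
  p <- phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  if (go_mode && k <= 1) p <- NA_real_
  list(k = k, K = K, m = m, N = N, p = p, overlap_genes = ov)
}

#' Enrichment of modules against gene-set collections
#'
#' Runs [overrepresentation_test()] for every (module, set) pair and applies
#' BH within the declared family: across all tests of the cell type
#' (`fdr_scope = "cell_type"`, the effector-set convention) or within each
#' module (`fdr_scope = "module"`, the GO convention). In GO mode, pairs
#' with a single overlapping gene are removed before adjustment.
#'
#' @param module_set a `module_set` (or named list of gene-id vectors).
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene ids; by default the union of module and
#'   unassigned genes (all genes tested for differential expression).
#' @param fdr_scope `"cell_type"` or `"module"`.
#' @param go_mode drop one-gene overlaps.
#' @return data.frame: module, set, k, K, m, N, p, q, overlap_genes.
#' @export
enrich_modules <- function(module_set, collections, universe = NULL,
                           fdr_scope = c("cell_type", "module"),
                           go_mode = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  modules <- if (inherits(module_set, "module_set")) module_set$modules
  else module_set
  if (length(collections) == 0) stop("empty gene-set collection")
  if (is.null(universe)) {
    if (!inherits(module_set, "module_set"))
      stop("universe required when module_set is a bare list")
    universe <- names(module_set$membership)
  }
  rows <- list()
  for (mn in names(modules)) {
    for (sn in names(collections)) {
      r <- overrepresentation_test(modules[[mn]], collections[[sn]],
                                   universe, go_mode = go_mode)
      if (go_mode && is.na(r$p)) next
      rows[[length(rows) + 1]] <- data.frame(
        module = mn, set = sn, k = r$k, K = r$K, m = r$m, N = r$N,
        p = r$p, overlap_genes = paste(r$overlap_genes, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = character(), set = character(),
                      k = integer(), K = integer(), m = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      overlap_genes = character()))
  out <- do.call(rbind, rows)
  if (fdr_scope == "cell_type") {
    out$q <- bh_adjust(out$p)
  } else {
    out$q <- NA_real_
    for (mn in unique(out$module)) {
      i <- out$module == mn
      out$q[i] <- bh_adjust(out$p[i])
    }
  }
  out
}
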
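# Expression-guided calibration of the minimal peak fold-enrichment
# threshold: for each candidate threshold, compare the genes carrying at
# least one peak at or above it with a set of known modulated genes, via a
# one-sided hypergeometric (Fisher) enrichment test, and pick the threshold
# with the smallest p-value.

#' Build an expression modulation set
#'
#' @param up,down character vectors of up- and downregulated gene ids; must
#'   be disjoint.
#' @param universe_size total number of genes in the annotation universe
#'   (the Fisher test's population size).
#' @return list with `up`, `down`, `modulated` (their union) and
#'   `universe_size`.
#' @export
expression_set <- function(up, down, universe_size) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("expression_set: up and down gene sets must be disjoint")
  modulated <- c(up, down)
  if (length(modulated) > universe_size)
    stop("expression_set: more modulated genes than the universe size")
  list(up = up, down = down, modulated = modulated,
       universe_size = as.integer(universe_size))
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for X hypergeometric with `N` items of which `K` are
#' successes, drawing `n` — the one-sided ("greater") Fisher exact test on
#' the corresponding 2x2 table.  Computed in log space (via
#' [stats::phyper()]), so it survives gene universes of tens of thousands
#' and p-values far below double underflow of individual terms.
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return the tail probability.
#' @export
hypergeom_tail_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("hypergeom_tail_p: need 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overlap statistics at one fold-enrichment threshold
#'
#' Restricts to peaks with fold enrichment at or above `t`, collects the
#' distinct genes they associate to, and tabulates the overlap with the
#' modulated set: `pct_mod` = percentage of modulated genes carrying a peak,
#' `pct_all` = percentage of the whole gene universe carrying a peak,
#' `enrichment_ratio` = their ratio (`NA` when `pct_all` is 0), and
#' `fisher_p` = the exact test on the 2x2 table
#' (peak-bearing vs not) x (modulated vs rest of universe).
#'
#' @param t fold-enrichment threshold (inclusive: FE >= t).
#' @param associations output of [associate_closest_tss()] (must carry
#'   `fold_enrichment`).
#' @param expr expression set from [expression_set()].
#' @param alternative `"greater"` (one-sided enrichment, the default) or
#'   `"two.sided"` (via [stats::fisher.test()]).
#' @return one-row data.frame: `threshold`, `n_peaks`, `n_genes`,
#'   `n_mod_overlap`, `pct_mod`, `pct_all`, `enrichment_ratio`, `fisher_p`.
#' @export
calibration_row <- function(t, associations, expr,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sel <- !is.na(associations$gene_id) & associations$fold_enrichment >= t
  n_peaks <- sum(associations$fold_enrichment >= t)
  genes <- unique(associations$gene_id[sel])
  n_genes <- length(genes)
  N <- expr$universe_size
  if (N < n_genes)
    stop("calibration_row: universe_size smaller than the associated gene count")
  K <- length(expr$modulated)
  k <- sum(expr$modulated %in% genes)
  pct_mod <- if (K > 0) 100 * k / K else NA_real_
  pct_all <- 100 * n_genes / N
  ratio <- if (pct_all > 0) pct_mod / pct_all else NA_real_
  p <- if (alternative == "greater") {
    hypergeom_tail_p(k, K, n_genes, N)
  } else {
    stats::fisher.test(matrix(c(k, K - k, n_genes - k,
                                N - K - (n_genes - k)), nrow = 2))$p.value
  }
  data.frame(threshold = t, n_peaks = n_peaks, n_genes = n_genes,
             n_mod_overlap = k, pct_mod = pct_mod, pct_all = pct_all,
             enrichment_ratio = ratio, fisher_p = p)
}

#' Fold-enrichment grid used by the threshold sweep
#'
#' Generated by integer index (`grid_min + i * grid_step`) so repeated
#' addition cannot drift; the default is 3.0 to 7.0 in 0.1 steps, endpoints
#' inclusive (41 values).
#'
#' @param grid_min,grid_max,grid_step grid limits and step.
#' @return numeric vector of thresholds.
#' @export
fe_grid <- function(grid_min = 3, grid_max = 7, grid_step = 0.1) {
  n <- round((grid_max - grid_min) / grid_step)
  if (n < 0) stop("fe_grid: empty grid")
  grid_min + (0:n) * grid_step
}

#' Sweep fold-enrichment thresholds and select the most enriched one
#'
#' Computes a [calibration_row()] at every grid value and selects the
#' threshold minimizing the Fisher p-value; exact ties go to the larger
#' (more stringent) threshold.
#'
#' @param associations output of [associate_closest_tss()].
#' @param expr expression set from [expression_set()].
#' @param grid ascending numeric vector of thresholds (default [fe_grid()]).
#' @param alternative passed to [calibration_row()].
#' @return list with `rows` (one data.frame row per grid value, plus a
#'   `selected` flag) and `selected_threshold`.
#' @export
sweep_thresholds <- function(associations, expr, grid = fe_grid(),
                             alternative = "greater") {
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("sweep_thresholds: grid must be non-empty and strictly ascending")
  rows <- do.call(rbind, lapply(grid, calibration_row,
                                associations = associations, expr = expr,
                                alternative = alternative))
  best_p <- min(rows$fisher_p)
  sel <- max(which(rows$fisher_p == best_p))   # tie -> larger threshold
  rows$selected <- seq_len(nrow(rows)) == sel
  list(rows = rows, selected_threshold = grid[sel])
}
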
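#' Run the full temporal-pattern pipeline on a count experiment
#'
#' Normalizes the counts, runs the three differential-expression comparisons
#' against sham, applies the mean/SD quantile filter, picks the clustering
#' gene universe (genes significant at 60 dpi vs sham intersected with the
#' filtered set when `config$restrict_to_chronic_de`, otherwise the filtered
#' set), and runs the cutoff sensitivity scan.
#'
#' @param m a [count_matrix()].
#' @param config a [run_config()].
#' @return a list with `factors`, `normalized`, `de` (named list of `tg_de`
#'   tables), `filtered` (gene ids passing the quantile filter), `universe`
#'   (gene ids clustered), and `scan` (a `tg_scan`).
#' @export
run_pipeline <- function(m, config = run_config()) {
  stopifnot(inherits(m, "tg_counts"))
  f <- compute_factors(m, background_method = config$background_method)
  nm <- normalize_counts(m, f)
  de <- lapply(tg_comparisons(), function(cmp) run_comparison(m, f, cmp, config))
  names(de) <- tg_comparisons()
  filtered <- filter_quantile(nm, config$filter_quantile)
  universe <- if (config$restrict_to_chronic_de) {
    significant_genes(de$d60_vs_sham)
  } else filtered
  if (length(universe) == 0)
    stop("clustering universe is empty; consider restrict_to_chronic_de = FALSE")
  scan <- sensitivity_scan(nm, universe, config)
  list(factors = f, normalized = nm, de = de, filtered = filtered,
       universe = universe, scan = scan)
}
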
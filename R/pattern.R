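#' Filter genes by expression level and variability
#'
#' Computes each gene's mean and standard deviation across all samples of the
#' normalized matrix and retains genes strictly above the `q`-th quantile of
#' both statistics. Quantiles use R's default linear interpolation between
#' order statistics (type 7); genes exactly at a threshold are excluded.
#'
#' @param nm a `tg_norm` object from [normalize_counts()].
#' @param q quantile in (0,1); default 0.25.
#' @return character vector of retained gene ids (input order).
#' @export
filter_quantile <- function(nm, q = 0.25) {
  stopifnot(inherits(nm, "tg_norm"), q > 0, q < 1)
  if (nrow(nm$values) == 0) stop("normalized matrix is empty")
  mu <- rowMeans(nm$values)
  sd_ <- apply(nm$values, 1, stats::sd)
  keep <- mu > stats::quantile(mu, q) & sd_ > stats::quantile(sd_, q)
  if (!any(keep)) stop("quantile filter removed every gene")
  rownames(nm$values)[keep]
}

#' Min-max standardize per-gene group-mean trajectories
#'
#' Averages normalized expression within each study group (sham, d2, d14,
#' d60) and rescales each gene's four group means to \[0,1\]. A gene whose
#' four group means are identical cannot be rescaled and is flagged
#' degenerate (standardized values all zero).
#'
#' @param nm a `tg_norm` object.
#' @param genes gene ids to include (default: all rows).
#' @return a list of class `tg_series` with `group_means` (genes x 4),
#'   `standardized` (genes x 4) and `degenerate` (logical per gene).
#' @export
standardize_series <- function(nm, genes = rownames(nm$values)) {
  stopifnot(inherits(nm, "tg_norm"))
  if (any(table(nm$group) < 1)) stop("every group needs at least one sample")
  miss <- setdiff(genes, rownames(nm$values))
  if (length(miss) > 0) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  v <- nm$values[genes, , drop = FALSE]
  gm <- sapply(tg_groups(), function(g) rowMeans(v[, nm$group == g, drop = FALSE]))
  gm <- matrix(gm, nrow = length(genes), dimnames = list(genes, tg_groups()))
  lo <- apply(gm, 1, min); hi <- apply(gm, 1, max)
  degenerate <- hi == lo
  std <- (gm - lo) / ifelse(degenerate, 1, hi - lo)
  std[degenerate, ] <- 0
  structure(list(group_means = gm, standardized = std, degenerate = degenerate),
            class = "tg_series")
}

#' Standardized linear changes (SLCs)
#'
#' Differences of the standardized trajectory over the three consecutive
#' intervals (sham to 2 dpi, 2 to 14 dpi, 14 to 60 dpi). For each gene the
#' interval with the largest absolute SLC is recorded (ties broken toward the
#' earliest interval) along with the absolute relative SLCs
#' `|SLC_i / SLC_max|` of the two remaining intervals.
#'
#' @param s a `tg_series` from [standardize_series()].
#' @return a list of class `tg_slc` with `slc` (genes x 3), `max_interval`
#'   (1-3, `NA` for degenerate genes), `slc_max`, `rel_slc` (genes x 3,
#'   `NA` at the maximal interval) and `degenerate`.
#' @export
compute_slc <- function(s) {
  stopifnot(inherits(s, "tg_series"))
  std <- s$standardized
  slc <- std[, 2:4, drop = FALSE] - std[, 1:3, drop = FALSE]
  colnames(slc) <- c("sham_to_d2", "d2_to_d14", "d14_to_d60")
  max_interval <- apply(abs(slc), 1, which.max)  # earliest on ties
  max_interval[s$degenerate] <- NA_integer_
  slc_max <- slc[cbind(seq_len(nrow(slc)), max_interval)]
  slc_max[s$degenerate] <- NA_real_
  rel <- abs(slc / slc_max)
  rel[cbind(seq_len(nrow(rel)), max_interval)] <- NA_real_
  structure(list(slc = slc, max_interval = max_interval, slc_max = slc_max,
                 rel_slc = rel, degenerate = s$degenerate),
            class = "tg_slc")
}

#' Assign per-interval sub-patterns from SLC profiles
#'
#' The maximal interval is labeled `up` or `down` by the sign of its SLC.
#' Each other interval is labeled by its absolute relative SLC: above
#' `cutoff_high` it is `up`/`down` according to its own SLC sign, below
#' `cutoff_low` it is `stable`, otherwise (including exact equality with
#' either cutoff) `noisy`. Degenerate genes get `(stable, stable, stable)`.
#'
#' @param p a `tg_slc` from [compute_slc()].
#' @param cutoff_high,cutoff_low cutoffs with `0 < cutoff_low < cutoff_high < 1`.
#' @return character matrix (genes x 3) over up/down/stable/noisy.
#' @export
assign_subpatterns <- function(p, cutoff_high, cutoff_low) {
  stopifnot(inherits(p, "tg_slc"))
  if (!(cutoff_low > 0 && cutoff_low < cutoff_high && cutoff_high < 1))
    stop("cutoffs must satisfy 0 < cutoff_low < cutoff_high < 1")
  n <- nrow(p$slc)
  out <- matrix("noisy", n, 3, dimnames = dimnames(p$slc))
  rel <- p$rel_slc
  dirn <- ifelse(p$slc > 0, "up", "down")
  out[!is.na(rel) & rel > cutoff_high] <- dirn[!is.na(rel) & rel > cutoff_high]
  out[!is.na(rel) & rel < cutoff_low] <- "stable"
  mx <- cbind(seq_len(n), p$max_interval)
  ok <- !p$degenerate
  out[mx[ok, , drop = FALSE]] <- ifelse(p$slc_max[ok] > 0, "up", "down")
  out[p$degenerate, ] <- "stable"
  out
}

#' Enumerate the pattern space
#'
#' All 64 ordered triples over the four sub-pattern labels, as pattern
#' strings (`"up-stable-stable"`, ...) in lexicographic order.
#'
#' @return character vector of length 64.
#' @export
enumerate_patterns <- function() {
  lab <- sort(c("up", "down", "stable", "noisy"))
  g <- expand.grid(third = lab, second = lab, first = lab,
                   stringsAsFactors = FALSE)
  paste(g$first, g$second, g$third, sep = "-")
}

#' Group genes into pattern clusters and count meaningful ones
#'
#' Genes sharing an identical sub-pattern triple form a cluster. `K1` counts
#' the nonempty clusters whose pattern contains no noisy interval; `K2`
#' counts those with no opposite directions (not both up and down);
#' `meaningful` counts clusters satisfying both.
#'
#' @param assignments character matrix (genes x 3) from
#'   [assign_subpatterns()], with gene ids as row names.
#' @return a list of class `tg_clusters` with `clusters` (named list,
#'   pattern string to gene ids), `patterns` (pattern string per gene),
#'   `K1`, `K2`, `meaningful`.
#' @export
cluster_genes <- function(assignments) {
  if (is.null(dim(assignments)) || nrow(assignments) == 0)
    stop("assignments must be a nonempty genes x 3 matrix")
  pat <- apply(assignments, 1, paste, collapse = "-")
  clusters <- split(rownames(assignments), pat)
  has_noisy <- grepl("noisy", names(clusters))
  opposite <- grepl("up", names(clusters)) & grepl("down", names(clusters))
  structure(list(clusters = clusters, patterns = pat,
                 K1 = sum(!has_noisy), K2 = sum(!opposite),
                 meaningful = sum(!has_noisy & !opposite)),
            class = "tg_clusters")
}

#' The p-measurement cutoff score
#'
#' `p_measurement = w / c * K1 * K2` with weight
#' `w = 1 / (cutoff_high * cutoff_low)`.
#'
#' @param cutoff_high,cutoff_low cutoffs in (0,1).
#' @param K1,K2 cluster counts (see [cluster_genes()]).
#' @param c positive scaling constant.
#' @return nonnegative score.
#' @export
p_measurement <- function(cutoff_high, cutoff_low, K1, K2, c = 1) {
  if (any(cutoff_high <= 0) || any(cutoff_low <= 0))
    stop("cutoffs must be positive")
  stopifnot(c > 0)
  (1 / (cutoff_high * cutoff_low)) / c * K1 * K2
}

#' Cutoff sensitivity scan
#'
#' Evaluates every pair on the configured cutoff grids: assigns sub-patterns,
#' clusters genes, and scores the pair by [p_measurement()]. The selected
#' pair maximizes the score; ties are broken toward the larger
#' `cutoff_high`, then the smaller `cutoff_low`.
#'
#' @param nm a `tg_norm` object.
#' @param genes gene ids to cluster (the gene universe).
#' @param config a [run_config()] supplying the grids and `c_constant`.
#' @return a list of class `tg_scan` with `grid` (data.frame: cutoff_high,
#'   cutoff_low, K1, K2, w, p_measurement), `selected` (one row of `grid`),
#'   `assignments` and `clusters` at the selected cutoffs, and the `slc`
#'   profile used.
#' @export
sensitivity_scan <- function(nm, genes, config = run_config()) {
  stopifnot(inherits(nm, "tg_norm"))
  if (length(genes) == 0) stop("empty gene universe")
  slc <- compute_slc(standardize_series(nm, genes))
  grid <- expand.grid(cutoff_low = config$cutoff_low_grid,
                      cutoff_high = config$cutoff_high_grid)[, 2:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ch <- grid$cutoff_high[i]; cl <- grid$cutoff_low[i]
    cls <- cluster_genes(assign_subpatterns(slc, ch, cl))
    data.frame(cutoff_high = ch, cutoff_low = cl, K1 = cls$K1, K2 = cls$K2,
               w = 1 / (ch * cl),
               p_measurement = p_measurement(ch, cl, cls$K1, cls$K2, config$c_constant))
  })
  grid <- do.call(rbind, rows)
  ord <- order(-grid$p_measurement, -grid$cutoff_high, grid$cutoff_low)
  selected <- grid[ord[1], ]
  assignments <- assign_subpatterns(slc, selected$cutoff_high, selected$cutoff_low)
  structure(list(grid = grid, selected = selected,
                 assignments = assignments,
                 clusters = cluster_genes(assignments), slc = slc),
            class = "tg_scan")
}

#' @export
print.tg_scan <- function(x, ...) {
  cat(sprintf("tg_scan: %d cutoff pairs over %d genes\n",
              nrow(x$grid), nrow(x$assignments)))
  cat(sprintf("  selected: cutoff_high=%.3g cutoff_low=%.3g (K1=%d, K2=%d, p_measurement=%.4g)\n",
              x$selected$cutoff_high, x$selected$cutoff_low,
              x$selected$K1, x$selected$K2, x$selected$p_measurement))
  invisible(x)
}
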
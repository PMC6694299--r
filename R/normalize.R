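# Geometric mean with zero counts replaced by 0.5 before the log, so that
# sporadic zero control probes do not send the mean to zero while nonzero
# counts keep the estimator exactly scale-equivariant.
.geomean <- function(x) exp(mean(log(pmax(x, 0.5))))

#' Compute control-based normalization factors
#'
#' Three per-sample quantities in the conventional nCounter order:
#' a positive-control scaling factor (geometric mean of the positive-control
#' counts, renormalized to geometric mean one across samples), a background
#' level from the negative controls, and a housekeeping content factor
#' computed on the positive/background-corrected housekeeping counts (again
#' renormalized to geometric mean one).
#'
#' @param m a [count_matrix()] with at least 2 positive, 1 negative and 2
#'   housekeeping genes.
#' @param background_method `"mean"` (default) or `"mean_plus_2sd"` of the
#'   negative-control counts.
#' @return a list of class `tg_factors` with per-sample vectors
#'   `positive_factor`, `background_level`, `housekeeping_factor`.
#' @export
compute_factors <- function(m, background_method = c("mean", "mean_plus_2sd")) {
  stopifnot(inherits(m, "tg_counts"))
  background_method <- match.arg(background_method)
  pos <- m$counts[m$gene_class == "positive", , drop = FALSE]
  neg <- m$counts[m$gene_class == "negative", , drop = FALSE]
  hk <- m$counts[m$gene_class == "housekeeping", , drop = FALSE]
  if (nrow(pos) < 2) stop("need at least 2 positive-control genes")
  if (nrow(neg) < 1) stop("need at least 1 negative-control gene")
  if (nrow(hk) < 2) stop("need at least 2 housekeeping genes")
  for (cls in list(pos, hk)) {
    dead <- rownames(cls)[rowSums(cls) == 0]
    if (length(dead) > 0)
      stop("control gene(s) with zero counts in every sample: ",
           paste(dead, collapse = ", "))
  }
  pos_raw <- apply(pos, 2, .geomean)
  positive_factor <- pos_raw / .geomean(pos_raw)
  background_level <- switch(background_method,
    mean = colMeans(neg),
    mean_plus_2sd = colMeans(neg) + 2 * apply(neg, 2, stats::sd))
  hk_corr <- sweep(hk, 2, positive_factor, "/")
  hk_corr <- pmax(sweep(hk_corr, 2, background_level, "-"), 0)
  hk_raw <- apply(hk_corr, 2, .geomean)
  housekeeping_factor <- hk_raw / .geomean(hk_raw)
  structure(list(positive_factor = positive_factor,
                 background_level = background_level,
                 housekeeping_factor = housekeeping_factor),
            class = "tg_factors")
}

#' Normalize endogenous counts with precomputed factors
#'
#' For each endogenous gene g and sample s:
#' `value = max(0, count / positive_factor_s - background_level_s) /
#' housekeeping_factor_s`. Control rows are dropped. Pure function of its
#' inputs.
#'
#' @param m the [count_matrix()] the factors were computed from.
#' @param f a `tg_factors` object from [compute_factors()].
#' @return a list of class `tg_norm` with `values` (endogenous genes x
#'   samples, nonnegative), `group` (per-sample factor) and `factors`
#'   (the provenance `f`).
#' @export
normalize_counts <- function(m, f) {
  stopifnot(inherits(m, "tg_counts"), inherits(f, "tg_factors"))
  if (any(f$positive_factor <= 0) || any(f$housekeeping_factor <= 0))
    stop("normalization factors must be positive")
  if (any(f$background_level < 0)) stop("background level must be nonnegative")
  endo <- m$counts[m$gene_class == "endogenous", , drop = FALSE]
  v <- sweep(endo, 2, f$positive_factor, "/")
  v <- pmax(sweep(v, 2, f$background_level, "-"), 0)
  v <- sweep(v, 2, f$housekeeping_factor, "/")
  structure(list(values = v, group = m$group, factors = f), class = "tg_norm")
}

#' @export
print.tg_norm <- function(x, ...) {
  cat(sprintf("tg_norm: %d endogenous genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
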
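.nb_ll <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = pmax(mu, 1e-10), log = TRUE))
}

# Fit a log-link NB GLM with fixed dispersion via IRLS; returns coefficients
# and fitted means. `x` is the design matrix, `off` the per-sample offset.
.nb_fit <- function(y, x, off, theta) {
  fit <- suppressWarnings(stats::glm.fit(x, y, offset = off,
                                         family = MASS::negative.binomial(theta)))
  list(coef = fit$coefficients, mu = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

# Cox-Reid adjusted profile log-likelihood of a fixed dispersion for one gene
# under the full (group) model: penalizes the likelihood by half the log
# determinant of the expected information of the fitted means, accounting for
# the mean parameters estimated at tiny n.
.cr_apl <- function(theta, y, x, off) {
  f <- .nb_fit(y, x, off, theta)
  w <- f$mu / (1 + f$mu / theta)
  xtwx <- crossprod(x, x * w)
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  .nb_ll(y, f$mu, theta) - 0.5 * as.numeric(ld)
}

# Method-of-moments dispersion from a single count vector, floored; used as
# the fallback when likelihood optimization is unavailable or degenerate.
.mom_theta <- function(y) {
  m <- mean(y); v <- stats::var(y)
  if (!is.finite(v) || v <= m) return(1e8)
  max(m^2 / (v - m), 1e-8)
}

#' Estimate the NB dispersion for a panel of genes
#'
#' Maximizes the Cox-Reid adjusted profile likelihood of a common dispersion
#' pooled across all genes (`method = "common"`, default) or per gene
#' (`method = "per_gene"`), under the two-group model with offsets. Genes
#' with all-zero counts are skipped. Falls back to a method-of-moments
#' estimate when optimization fails.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups two-level factor over samples.
#' @param offsets per-sample log offsets (default zero).
#' @param method `"common"` or `"per_gene"`.
#' @return for `"common"`, a single dispersion (theta); for `"per_gene"`,
#'   a vector with one theta per gene.
#' @export
estimate_dispersion <- function(counts, groups, offsets = NULL,
                                method = c("common", "per_gene")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  if (is.null(offsets)) offsets <- rep(0, ncol(counts))
  x <- stats::model.matrix(~groups)
  use <- rowSums(counts) > 0
  if (!any(use)) stop("no gene with nonzero counts")
  if (method == "common") {
    obj <- function(lth) {
      th <- exp(lth)
      sum(apply(counts[use, , drop = FALSE], 1, function(y)
        tryCatch(.cr_apl(th, y, x, offsets), error = function(e) 0)))
    }
    opt <- tryCatch(stats::optimize(obj, c(log(1e-4), log(1e6)), maximum = TRUE),
                    error = function(e) NULL)
    if (is.null(opt)) return(stats::median(apply(counts[use, , drop = FALSE], 1, .mom_theta)))
    exp(opt$maximum)
  } else {
    th <- apply(counts, 1, function(y) {
      if (sum(y) == 0) return(NA_real_)
      opt <- tryCatch(
        stats::optimize(function(lth) .cr_apl(exp(lth), y, x, offsets),
                        c(log(1e-4), log(1e6)), maximum = TRUE),
        error = function(e) NULL)
      if (is.null(opt)) .mom_theta(y) else exp(opt$maximum)
    })
    th
  }
}

#' Negative-binomial GLM test for one gene
#'
#' Fits `log mu = b0 + b1 * I(treatment) + offset` with NB errors and a fixed
#' dispersion, and tests `b1 = 0` by the likelihood-ratio test against the
#' intercept-only model (chi-square, 1 df). If `theta` is not supplied it is
#' estimated for this gene by Cox-Reid adjusted profile likelihood with a
#' method-of-moments fallback.
#'
#' @param counts nonnegative integer vector over samples.
#' @param groups two-level factor; the first level is the reference.
#' @param offsets per-sample log normalization offsets (default zero).
#' @param theta fixed NB dispersion (size); `NULL` to estimate per gene.
#' @return list with `log2fc`, `pvalue`, `theta`, and `flag`
#'   (`"ok"`, `"untestable"` or `"fallback"`).
#' @export
fit_nb_glm <- function(counts, groups, offsets = NULL, theta = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  if (any(table(groups) < 2)) stop("need at least 2 samples per group")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(offsets)) offsets <- rep(0, length(counts))
  if (all(counts == 0))
    return(list(log2fc = 0, pvalue = 1, theta = NA_real_, flag = "untestable"))
  x <- stats::model.matrix(~groups)
  if (is.null(theta)) {
    opt <- tryCatch(
      stats::optimize(function(lth) .cr_apl(exp(lth), counts, x, offsets),
                      c(log(1e-4), log(1e6)), maximum = TRUE),
      error = function(e) NULL)
    theta <- if (is.null(opt)) .mom_theta(counts) else exp(opt$maximum)
  }
  res <- tryCatch({
    full <- .nb_fit(counts, x, offsets, theta)
    null <- .nb_fit(counts, x[, 1, drop = FALSE], offsets, theta)
    lrt <- max(0, 2 * (.nb_ll(counts, full$mu, theta) - .nb_ll(counts, null$mu, theta)))
    list(log2fc = full$coef[2] / log(2),
         pvalue = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
         flag = if (full$converged) "ok" else "fallback")
  }, error = function(e) NULL)
  if (is.null(res)) {
    # direct moment fallback: offset-corrected group means and a fixed-theta LRT
    rate <- counts / exp(offsets)
    mA <- mean(rate[groups == levels(groups)[1]]) + 0.5
    mB <- mean(rate[groups == levels(groups)[2]]) + 0.5
    muF <- ifelse(groups == levels(groups)[1], mA, mB) * exp(offsets)
    mu0 <- mean(rate) * exp(offsets)
    lrt <- max(0, 2 * (.nb_ll(counts, muF, theta) - .nb_ll(counts, mu0, theta)))
    res <- list(log2fc = log2(mB / mA),
                pvalue = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                flag = "fallback")
  }
  list(log2fc = unname(res$log2fc), pvalue = unname(res$pvalue),
       theta = theta, flag = res$flag)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression of one time point against sham
#'
#' Runs the per-gene NB GLM over all endogenous genes for one comparison.
#' Counts enter raw; normalization enters through per-sample offsets
#' `log(positive_factor * housekeeping_factor)`, with the background level
#' absorbed by the gene-wise intercept. Dispersion is pooled across the panel
#' by default (see [estimate_dispersion()]).
#'
#' @param m a [count_matrix()].
#' @param f a `tg_factors` object from [compute_factors()].
#' @param comparison one of `r paste(tg_comparisons(), collapse=", ")`.
#' @param config a [run_config()]; uses `fdr_threshold` and
#'   `dispersion_method`.
#' @return a data.frame of class `tg_de` with columns `gene_id`, `log2fc`,
#'   `pvalue`, `qvalue`, `direction`, `flag`; the comparison name is stored
#'   in `attr(, "comparison")`.
#' @export
run_comparison <- function(m, f, comparison, config = run_config()) {
  stopifnot(inherits(m, "tg_counts"), inherits(f, "tg_factors"))
  comparison <- match.arg(comparison, tg_comparisons())
  trt <- sub("_vs_sham$", "", comparison)
  keep <- m$group %in% c("sham", trt)
  if (sum(m$group == trt) == 0 || sum(m$group == "sham") == 0)
    stop("comparison ", comparison, " requires samples in both groups")
  cnt <- m$counts[m$gene_class == "endogenous", keep, drop = FALSE]
  grp <- factor(as.character(m$group[keep]), levels = c("sham", trt))
  off <- log(f$positive_factor * f$housekeeping_factor)[keep]
  theta <- if (config$dispersion_method == "common") {
    estimate_dispersion(cnt, grp, off, method = "common")
  } else {
    estimate_dispersion(cnt, grp, off, method = "per_gene")
  }
  n <- nrow(cnt)
  log2fc <- numeric(n); pvalue <- numeric(n); flag <- character(n)
  for (i in seq_len(n)) {
    th_i <- if (length(theta) == 1) theta else theta[i]
    if (is.na(th_i)) th_i <- NULL
    r <- fit_nb_glm(cnt[i, ], grp, off, theta = th_i)
    log2fc[i] <- r$log2fc; pvalue[i] <- r$pvalue; flag[i] <- r$flag
  }
  out <- data.frame(gene_id = rownames(cnt), log2fc = log2fc, pvalue = pvalue,
                    qvalue = bh_adjust(pvalue),
                    direction = ifelse(log2fc > 0, "up", "down"),
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  attr(out, "fdr_threshold") <- config$fdr_threshold
  class(out) <- c("tg_de", "data.frame")
  out
}

#' Genes significant in a DE result
#'
#' @param de a `tg_de` table from [run_comparison()].
#' @param fdr threshold on the adjusted p-value (default: the threshold the
#'   table was produced with).
#' @return character vector of significant gene ids.
#' @export
significant_genes <- function(de, fdr = attr(de, "fdr_threshold")) {
  stopifnot(inherits(de, "tg_de"))
  de$gene_id[de$qvalue < fdr]
}
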
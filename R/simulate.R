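#' Default planted pattern specification
#'
#' Three planted temporal clusters mirroring the chronic-phase cluster sizes
#' reported for this injury model: 52 genes stable through 2 and 14 dpi then
#' upregulated at 60 dpi, 8 genes rising from 14 dpi onward, and 5 genes
#' stable until a chronic downregulation; all with 4-fold amplitude.
#'
#' @return a list of `list(pattern, n, amplitude)` entries.
#' @export
default_pattern_spec <- function() {
  list(
    list(pattern = c("stable", "stable", "up"),   n = 52L, amplitude = 4),
    list(pattern = c("stable", "up", "up"),       n = 8L,  amplitude = 4),
    list(pattern = c("stable", "stable", "down"), n = 5L,  amplitude = 4)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic count experiment. Defaults reproduce the study
#' design the package targets: a ~550-gene inflammation/immunity panel with
#' nCounter-style controls, group sizes sham 4 / 2 dpi 4 / 14 dpi 4 / 60 dpi
#' 3, negative-binomial counts with moderate overdispersion, log-normal
#' lane-to-lane technical factors and a small additive background.
#'
#' @param n_endogenous,n_housekeeping,n_positive,n_negative panel composition.
#' @param group_sizes named integer vector over `sham, d2, d14, d60`.
#' @param dispersion NB size parameter (larger = less overdispersed).
#' @param lane_factor_sd SD of log lane factors.
#' @param background_mean mean additive background count per probe.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline expression.
#' @param pattern_spec list of `list(pattern, n, amplitude)` planted pattern
#'   blocks; each `pattern` is a triple over up/down/stable/noisy containing
#'   at least one up or down entry, and `amplitude > 1` is the max/min fold
#'   change of the planted trajectory. Remaining endogenous genes are flat.
#' @param seed integer seed.
#' @return a list of class `tg_sim_config`.
#' @export
sim_config <- function(n_endogenous = 550L,
                       n_housekeeping = 6L,
                       n_positive = 6L,
                       n_negative = 8L,
                       group_sizes = c(sham = 4L, d2 = 4L, d14 = 4L, d60 = 3L),
                       dispersion = 10,
                       lane_factor_sd = 0.2,
                       background_mean = 5,
                       baseline_log_mean = log(200),
                       baseline_log_sd = 1.0,
                       pattern_spec = default_pattern_spec(),
                       seed = 1L) {
  stopifnot(n_endogenous > 0, n_housekeeping > 0, n_positive > 0, n_negative > 0,
            dispersion > 0, lane_factor_sd >= 0, background_mean >= 0)
  if (!setequal(names(group_sizes), tg_groups()))
    stop("group_sizes must be named exactly ", paste(tg_groups(), collapse = ", "))
  if (any(group_sizes <= 0)) stop("all group sizes must be positive")
  n_planted <- 0L
  for (blk in pattern_spec) {
    if (!all(c("pattern", "n", "amplitude") %in% names(blk)))
      stop("each pattern_spec entry needs fields pattern, n, amplitude")
    if (length(blk$pattern) != 3 || !all(blk$pattern %in% c("up", "down", "stable", "noisy")))
      stop("pattern must be a triple over up/down/stable/noisy")
    if (!any(blk$pattern %in% c("up", "down")))
      stop("a planted pattern must contain at least one up or down interval ",
           "(the maximal interval is always labeled by direction)")
    if (blk$amplitude <= 1) stop("amplitude must be > 1 for a non-flat pattern")
    n_planted <- n_planted + as.integer(blk$n)
  }
  if (n_planted > n_endogenous)
    stop("pattern_spec plants more genes than n_endogenous")
  structure(list(
    n_endogenous = as.integer(n_endogenous),
    n_housekeeping = as.integer(n_housekeeping),
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    group_sizes = group_sizes[tg_groups()],
    dispersion = dispersion,
    lane_factor_sd = lane_factor_sd,
    background_mean = background_mean,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    pattern_spec = pattern_spec,
    seed = as.integer(seed)
  ), class = "tg_sim_config")
}

# Relative magnitudes used to realize planted sub-patterns. The first up/down
# entry carries the maximal change; further up/down entries use 0.9 (above the
# largest scanned cutoff_high, 0.75); stable intervals are exactly flat; noisy
# intervals use 0.2875, inside the noisy band (cutoff_low, cutoff_high) for
# every pair on the default grids.
.pattern_deltas <- function(pattern) {
  rel <- numeric(3)
  seen_main <- FALSE
  for (i in 1:3) {
    p <- pattern[i]
    if (p == "up" || p == "down") {
      mag <- if (!seen_main) 1 else 0.9
      seen_main <- TRUE
      rel[i] <- if (p == "up") mag else -mag
    } else if (p == "noisy") {
      rel[i] <- 0.2875
    } # stable -> 0
  }
  rel
}

# Group-mean trajectory over (sham, d2, d14, d60) realizing `pattern` with
# max/min fold change `amplitude`, minimum at `baseline`. Affine in the
# cumulative delta scores, so standardized differences keep the planted
# relative magnitudes exactly.
.pattern_means <- function(pattern, amplitude, baseline) {
  s <- c(0, cumsum(.pattern_deltas(pattern)))
  rng <- max(s) - min(s)
  baseline + (s - min(s)) / rng * baseline * (amplitude - 1)
}

.pattern_string <- function(p) paste(p, collapse = "-")

#' Simulate a NanoString-like count experiment with known ground truth
#'
#' Endogenous and housekeeping counts are drawn as
#' `NB(mean = lane_factor * group_mean + background, size = dispersion)`;
#' housekeeping group means are constant across groups; positive controls
#' follow a deterministic 6-point geometric concentration ladder scaled by
#' the lane factor plus Poisson background; negative controls are pure
#' Poisson background. Planted genes follow trajectories whose standardized
#' linear changes reproduce their labeled pattern exactly in expectation.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (a [count_matrix()]) and `truth`,
#'   where `truth` has `lane_factors`, `background` (per sample),
#'   `pattern` (per endogenous gene, a pattern string or `"flat"`),
#'   `group_means` (endogenous genes x 4 expected expression), and `de`
#'   (endogenous genes x 3 logical, whether the true mean differs from sham).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "tg_sim_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  groups <- rep(names(gs), times = gs)
  sample_ids <- unlist(lapply(names(gs), function(g) paste0(g, "_", seq_len(gs[[g]]))))
  n_s <- length(groups)

  lane <- exp(stats::rnorm(n_s, 0, config$lane_factor_sd))
  names(lane) <- sample_ids
  background <- stats::setNames(rep(config$background_mean, n_s), sample_ids)

  n_e <- config$n_endogenous
  endo_ids <- sprintf("gene_%04d", seq_len(n_e))
  baseline <- stats::rlnorm(n_e, config$baseline_log_mean, config$baseline_log_sd)

  pattern <- rep("flat", n_e)
  gm <- matrix(baseline, n_e, 4, dimnames = list(endo_ids, tg_groups()))
  i <- 1L
  for (blk in config$pattern_spec) {
    idx <- seq.int(i, length.out = blk$n)
    pattern[idx] <- .pattern_string(blk$pattern)
    for (j in idx) gm[j, ] <- .pattern_means(blk$pattern, blk$amplitude, baseline[j])
    i <- i + as.integer(blk$n)
  }

  hk_ids <- sprintf("hk_%02d", seq_len(config$n_housekeeping))
  hk_mean <- stats::rlnorm(config$n_housekeeping, config$baseline_log_mean,
                           config$baseline_log_sd)
  pos_ids <- sprintf("pos_%02d", seq_len(config$n_positive))
  ladder <- 32 * 128 / 4^(seq_len(config$n_positive) - 1)
  neg_ids <- sprintf("neg_%02d", seq_len(config$n_negative))

  cnt <- matrix(0L, n_e + length(hk_ids) + length(pos_ids) + length(neg_ids), n_s,
                dimnames = list(c(endo_ids, hk_ids, pos_ids, neg_ids), sample_ids))
  for (s in seq_len(n_s)) {
    mu_e <- lane[s] * gm[, groups[s]] + background[s]
    mu_h <- lane[s] * hk_mean + background[s]
    cnt[endo_ids, s] <- stats::rnbinom(n_e, mu = mu_e, size = config$dispersion)
    cnt[hk_ids, s] <- stats::rnbinom(length(hk_ids), mu = mu_h, size = config$dispersion)
    cnt[pos_ids, s] <- round(lane[s] * ladder) +
      stats::rpois(length(pos_ids), background[s])
    cnt[neg_ids, s] <- stats::rpois(length(neg_ids), background[s])
  }

  de <- cbind(d2_vs_sham = gm[, "d2"] != gm[, "sham"],
              d14_vs_sham = gm[, "d14"] != gm[, "sham"],
              d60_vs_sham = gm[, "d60"] != gm[, "sham"])
  cm <- count_matrix(cnt,
                     gene_class = rep(c("endogenous", "housekeeping", "positive", "negative"),
                                      times = c(n_e, length(hk_ids), length(pos_ids), length(neg_ids))),
                     group = groups)
  list(counts = cm,
       truth = list(lane_factors = lane, background = background,
                    pattern = stats::setNames(pattern, endo_ids),
                    group_means = gm, de = de))
}

#' Simulate a global-null experiment
#'
#' As [simulate_experiment()] with an empty pattern specification: every
#' endogenous gene is flat, so all true differential-expression indicators
#' are `FALSE`. Used to calibrate the differential-expression stage.
#'
#' @param config a [sim_config()]; its `pattern_spec` is ignored.
#' @return as [simulate_experiment()].
#' @export
simulate_null <- function(config = sim_config()) {
  stopifnot(inherits(config, "tg_sim_config"))
  config$pattern_spec <- list()
  simulate_experiment(config)
}
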
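# Independent oracles and hand-built fixtures shared across test files.
# Oracle code deliberately avoids the package's internals: scalar loops,
# direct likelihood evaluation, no reuse of tg_* helpers.

# Literal scalar transcription of the sub-pattern rule: the interval with the
# largest absolute SLC (earliest on ties) is up/down by sign; each other
# interval is up/down by its own sign if |SLC_i/SLC_max| > cutoff_high,
# stable if < cutoff_low, noisy otherwise.
oracle_assign <- function(slc, cutoff_high, cutoff_low) {
  out <- character(3)
  imax <- 1
  for (i in 2:3) if (abs(slc[i]) > abs(slc[imax])) imax <- i
  out[imax] <- if (slc[imax] > 0) "up" else "down"
  for (i in setdiff(1:3, imax)) {
    rel <- abs(slc[i] / slc[imax])
    if (rel > cutoff_high) {
      out[i] <- if (slc[i] > 0) "up" else "down"
    } else if (rel < cutoff_low) {
      out[i] <- "stable"
    } else {
      out[i] <- "noisy"
    }
  }
  out
}

# Brute-force NB likelihood-ratio test with fixed dispersion: maximizes the
# log-likelihood by direct 1-d optimization of each group mean (full model)
# and the common mean (null model); no GLM machinery.
oracle_nb_lrt <- function(y, grp, theta) {
  ll <- function(yy, mu) sum(dnbinom(yy, size = theta, mu = mu, log = TRUE))
  opt_mu <- function(yy) {
    optimize(function(m) ll(yy, m), c(1e-6, max(yy) * 10 + 10), maximum = TRUE)
  }
  lv <- levels(grp)
  full <- opt_mu(y[grp == lv[1]])$objective + opt_mu(y[grp == lv[2]])$objective
  null <- opt_mu(y)$objective
  lrt <- max(0, 2 * (full - null))
  pchisq(lrt, df = 1, lower.tail = FALSE)
}

# Build a tg_series object directly from a matrix of standardized values,
# bypassing the group-mean pipeline, so SLC/assignment arithmetic can be
# tested on hand-picked trajectories.
series_from_std <- function(std) {
  std <- matrix(std, ncol = 4,
                dimnames = list(sprintf("g%02d", seq_len(length(std) / 4)),
                                tg_groups()))
  structure(list(group_means = std, standardized = std,
                 degenerate = apply(std, 1, function(r) all(r == r[1]))),
            class = "tg_series")
}

# tg_slc built from raw SLC triples (rows): standardized = cumulative sums.
slc_from_triples <- function(triples) {
  triples <- matrix(triples, ncol = 3)
  std <- t(apply(cbind(0, triples), 1, cumsum))
  compute_slc(series_from_std(std))
}

# Minimal tg_norm from a values matrix and per-sample groups.
norm_from_values <- function(values, group) {
  structure(list(values = values, group = factor(group, levels = tg_groups()),
                 factors = NULL), class = "tg_norm")
}

# A tiny hand-written count experiment with all four gene classes.
tiny_counts <- function() {
  cnt <- rbind(
    gA = c(100L, 120L, 90L, 110L),
    gB = c(10L, 15L, 12L, 9L),
    hk1 = c(500L, 510L, 495L, 505L),
    hk2 = c(300L, 290L, 310L, 305L),
    pos1 = c(4000L, 4100L, 3900L, 4000L),
    pos2 = c(1000L, 1020L, 990L, 1010L),
    neg1 = c(2L, 0L, 1L, 3L)
  )
  colnames(cnt) <- c("s1", "s2", "s3", "s4")
  count_matrix(cnt,
               gene_class = c("endogenous", "endogenous", "housekeeping",
                              "housekeeping", "positive", "positive", "negative"),
               group = c("sham", "d2", "d14", "d60"))
}

# Small simulation config used where full panel size is not the point.
small_sim <- function(seed = 1L, ...) {
  sim_config(n_endogenous = 60L, n_housekeeping = 4L, n_positive = 6L,
             n_negative = 6L,
             pattern_spec = list(
               list(pattern = c("stable", "stable", "up"), n = 10L, amplitude = 4)),
             seed = seed, ...)
}
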
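# Raw cross-correlogram counts: histogram of (t_b - t_a) in 1 ms bins over
# +/-window_ms. Bin k (ms) covers [k - 0.5, k + 0.5) ms.
ccg_counts <- function(a, b, window_ms = 500, bin_ms = 1) {
  w <- window_ms / 1000
  nb <- as.integer(window_ms / bin_ms)
  counts <- numeric(2L * nb + 1L)
  if (length(a) == 0 || length(b) == 0) return(counts)
  b <- sort(b)
  lo <- findInterval(a - w, b)            # b[lo] < a - w <= b[lo+1]
  hi <- findInterval(a + w, b)
  nper <- hi - lo
  keep <- nper > 0
  if (!any(keep)) return(counts)
  idx <- sequence(nper[keep]) + rep(lo[keep], nper[keep])
  diffs <- b[idx] - rep(a[keep], nper[keep])
  k <- floor(diffs * 1000 / bin_ms + 0.5)
  k <- k[k >= -nb & k <= nb]
  tab <- tabulate(as.integer(k + nb + 1L), nbins = 2L * nb + 1L)
  as.numeric(tab)
}

ccg_lags <- function(window_ms = 500, bin_ms = 1) {
  seq(-window_ms, window_ms, by = bin_ms)
}

new_ccg <- function(lags_ms, counts, ..., class = character()) {
  structure(c(list(lags_ms = lags_ms, counts = counts), list(...)),
            class = c(class, "ccg"))
}

#' @export
print.ccg <- function(x, ...) {
  cat("<ccg> ", length(x$lags_ms), " bins, peak ", signif(x$peak_value, 4),
      " at ", x$peak_lag_ms, " ms", sep = "")
  if (!is.null(x$sync_strength)) {
    cat(", sync strength ", signif(x$sync_strength, 3),
        ", p = ", signif(x$p_value, 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

# Restrict a spike train to state intervals (two-column start_s/end_s).
restrict_to_intervals <- function(spike_times, intervals) {
  if (is.null(intervals)) return(spike_times)
  spike_times[in_intervals(spike_times, intervals)]
}

#' Grand-average cross-correlogram of a reference cell vs the population
#'
#' Histogram of spike-time differences between a reference train and the
#' pooled spikes of all other cells (1 ms bins, +/-500 ms), normalized by the
#' number of reference spikes times the number of other cells. Optionally
#' restricted to a behavioral state (both spikes inside the state intervals).
#'
#' @param ref_spikes reference spike times (s).
#' @param other_trains list of the other cells' spike-time vectors.
#' @param window_ms CCG halfwidth (ms).
#' @param bin_ms bin width (ms).
#' @param state_intervals optional tibble of `start_s`, `end_s` intervals.
#' @return A `ccg` object with `lags_ms`, `counts` (normalized), `peak_lag_ms`,
#'   `peak_value`, `fwhm_ms`, `n_ref`, `n_other_cells`.
#' @export
grand_average_ccg <- function(ref_spikes, other_trains, window_ms = 500,
                              bin_ms = 1, state_intervals = NULL) {
  ref <- restrict_to_intervals(ref_spikes, state_intervals)
  others <- lapply(other_trains, restrict_to_intervals, state_intervals)
  if (length(ref) == 0) stop("undefined CCG: empty reference train", call. = FALSE)
  stopifnot(length(others) >= 1)
  pooled <- sort(unlist(others, use.names = FALSE))
  counts <- ccg_counts(ref, pooled, window_ms, bin_ms) /
    (length(ref) * length(others))
  lags <- ccg_lags(window_ms, bin_ms)
  pk <- ccg_peak(lags, counts, peak_halfwidth_ms = 30)
  g <- new_ccg(lags, counts, peak_lag_ms = pk$lag, peak_value = pk$value,
               n_ref = length(ref), n_other_cells = length(others),
               window_ms = window_ms, bin_ms = bin_ms)
  g$fwhm_ms <- tryCatch(ccg_fwhm(g), error = function(e) NA_real_)
  g
}

# Peak bin: maximum within +/-peak_halfwidth_ms; ties -> smallest |lag|,
# then negative lag before positive.
ccg_peak <- function(lags, counts, peak_halfwidth_ms = 30) {
  sel <- which(abs(lags) <= peak_halfwidth_ms)
  m <- max(counts[sel])
  cand <- sel[counts[sel] == m]
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  list(lag = lags[cand[1]], value = m, index = cand[1])
}

#' Average several CCGs into a session-level CCG
#'
#' Bin-wise mean of normalized counts across CCGs on the same lag grid (the
#' session-average grand CCG); peak and FWHM are recomputed on the average.
#'
#' @param ccgs list of `ccg` objects with identical lag grids.
#' @return A `ccg` object.
#' @export
average_ccgs <- function(ccgs) {
  stopifnot(length(ccgs) >= 1)
  lags <- ccgs[[1]]$lags_ms
  counts <- rowMeans(vapply(ccgs, function(g) g$counts,
                            numeric(length(lags))))
  pk <- ccg_peak(lags, counts, peak_halfwidth_ms = 30)
  g <- new_ccg(lags, counts, peak_lag_ms = pk$lag, peak_value = pk$value,
               n_averaged = length(ccgs),
               window_ms = ccgs[[1]]$window_ms, bin_ms = ccgs[[1]]$bin_ms)
  g$fwhm_ms <- tryCatch(ccg_fwhm(g), error = function(e) NA_real_)
  g
}

#' Full width at half maximum of a CCG peak
#'
#' The baseline is the mean of bins with `|lag| > baseline_min_ms`; the width
#' is measured at halfway between baseline and peak, with linear interpolation
#' between bins at the two crossings. The crossing search runs on the
#' 5-point-smoothed correlogram: single-bin counting noise otherwise places
#' spurious half-max crossings right next to the peak bin, making the width a
#' statistic of the noise rather than of the peak. Smoothing of this width
#' leaves the FWHM of peaks wider than a few bins essentially unchanged
#' (it adds ~2 ms^2 to the squared width of a Gaussian peak).
#'
#' @param ccg a `ccg` object.
#' @param baseline_min_ms bins beyond this |lag| form the baseline.
#' @return FWHM in milliseconds.
#' @export
ccg_fwhm <- function(ccg, baseline_min_ms = 400) {
  lags <- ccg$lags_ms
  counts <- moving_average(ccg$counts, 2L)
  if (ccg$peak_value <= stats::median(ccg$counts)) {
    stop("undefined FWHM: no peak above baseline", call. = FALSE)
  }
  base <- mean(counts[abs(lags) > baseline_min_ms])
  pk <- ccg_peak(lags, counts, peak_halfwidth_ms = 30)
  half <- base + (pk$value - base) / 2
  peak_i <- pk$index
  left <- NA_real_
  for (i in seq(peak_i, 2L)) {
    if (counts[i - 1L] <= half && counts[i] >= half) {
      frac <- (half - counts[i - 1L]) / (counts[i] - counts[i - 1L])
      left <- lags[i - 1L] + frac * (lags[i] - lags[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(peak_i, length(lags) - 1L)) {
    if (counts[i + 1L] <= half && counts[i] >= half) {
      frac <- (counts[i] - half) / (counts[i] - counts[i + 1L])
      right <- lags[i] + frac * (lags[i + 1L] - lags[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("undefined FWHM: no half-maximum crossings in window", call. = FALSE)
  }
  right - left
}

#' Cross-session shuffled grand-average CCG (flat null)
#'
#' Grand-average CCG of the reference train against `n_cells` trains drawn
#' without replacement from other sessions' cells.
#'
#' @param ref_spikes reference spike times (s).
#' @param other_sessions named list of sessions, each a list of spike trains;
#'   names identify sessions.
#' @param ref_session name of the reference cell's session (excluded).
#' @param n_cells number of trains to draw.
#' @param seed RNG seed.
#' @inheritParams grand_average_ccg
#' @return A `ccg` object.
#' @export
session_shuffle_control <- function(ref_spikes, other_sessions, ref_session,
                                    n_cells, seed, window_ms = 500,
                                    bin_ms = 1) {
  pool_sessions <- other_sessions[setdiff(names(other_sessions), ref_session)]
  if (length(pool_sessions) < 2) {
    stop("sampling error: need trains from at least 2 other sessions",
         call. = FALSE)
  }
  pool <- unlist(pool_sessions, recursive = FALSE, use.names = FALSE)
  if (length(pool) < n_cells) {
    stop("sampling error: pool smaller than n_cells", call. = FALSE)
  }
  draw <- with_seed(seed, sample.int(length(pool), n_cells))
  grand_average_ccg(ref_spikes, pool[draw], window_ms, bin_ms)
}

#' Pairwise cross-correlogram with jitter significance
#'
#' Raw CCG (1 ms bins, +/-500 ms) between two trains. Pairs with 100 or fewer
#' total counts in the window are excluded. The peak is the maximum within
#' +/-30 ms of lag; significance comes from jittering the target train within
#' +/-75 ms (`n_jitters` iterations): `p = (1 + #(jittered peaks >= observed))
#' / (1 + n_jitters)`. The synchronization strength is the observed peak
#' divided by the mean jittered count in the observed peak's bin.
#'
#' @param train_a reference spike train (s).
#' @param train_b target spike train (s; this train is jittered).
#' @param state_intervals optional state restriction (both trains).
#' @param n_jitters number of jitter iterations.
#' @param jitter_halfwidth_ms jitter halfwidth (ms).
#' @param seed RNG seed.
#' @param window_ms CCG halfwidth (ms).
#' @param min_counts inclusion threshold on total window counts.
#' @param peak_halfwidth_ms search halfwidth for the peak (ms).
#' @return A `ccg` object with `peak_lag_ms`, `peak_value`, `fwhm_ms`,
#'   `p_value`, `sync_strength`, `n_pair_counts`; or an object of class
#'   `ccg_excluded` carrying `excluded_reason`.
#' @export
pairwise_ccg <- function(train_a, train_b, state_intervals = NULL,
                         n_jitters = 1000, jitter_halfwidth_ms = 75, seed,
                         window_ms = 500, min_counts = 100,
                         peak_halfwidth_ms = 30) {
  a <- sort(restrict_to_intervals(train_a, state_intervals))
  b <- sort(restrict_to_intervals(train_b, state_intervals))
  counts <- ccg_counts(a, b, window_ms, 1)
  total <- sum(counts)
  if (total <= min_counts) {
    return(structure(list(excluded_reason = paste0(
      "insufficient counts (", total, " <= ", min_counts, ")"),
      n_pair_counts = total), class = "ccg_excluded"))
  }
  lags <- ccg_lags(window_ms, 1)
  pk <- ccg_peak(lags, counts, peak_halfwidth_ms)
  hw <- jitter_halfwidth_ms / 1000
  jit_window <- peak_halfwidth_ms  # jitter CCGs only needed within the peak search window
  nb <- as.integer(jit_window)
  obs_bin_jit <- as.integer(pk$lag + nb + 1L)
  n_ge <- 0L
  sum_at_bin <- 0
  with_seed(seed, {
    for (k in seq_len(n_jitters)) {
      bj <- b + stats::runif(length(b), -hw, hw)
      cj <- ccg_counts(a, bj, jit_window, 1)
      if (max(cj) >= pk$value) n_ge <- n_ge + 1L
      sum_at_bin <- sum_at_bin + cj[obs_bin_jit]
    }
  })
  p <- (1 + n_ge) / (1 + n_jitters)
  strength <- pk$value / (sum_at_bin / n_jitters)
  g <- new_ccg(lags, counts, peak_lag_ms = pk$lag, peak_value = pk$value,
               p_value = p, sync_strength = strength, n_pair_counts = total,
               n_jitters = n_jitters, window_ms = window_ms, bin_ms = 1)
  g$fwhm_ms <- tryCatch(ccg_fwhm(g), error = function(e) NA_real_)
  g
}

#' 5-point moving average for CCG display
#'
#' Display smoothing only, never used in statistics. Edge windows shrink so
#' interior mass is preserved.
#'
#' @param counts CCG counts per bin.
#' @return smoothed counts.
#' @export
smooth_for_display <- function(counts) {
  stopifnot(length(counts) >= 5)
  moving_average(counts, 2L)
}
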
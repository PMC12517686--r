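#' Label overlapping 1 s segments by behavioral state
#'
#' Segments `[k * 0.5, k * 0.5 + 1)` s (50% overlap). A segment is
#' "immobility" if speed stays below 1 cm/s for more than 90% of its samples,
#' "locomotion" if above 3 cm/s for more than 90%, otherwise "excluded".
#'
#' @param speed_cm_s speed series at the imaging rate.
#' @param sampling_rate_hz rate of the speed series.
#' @param seg_s segment length (s).
#' @param overlap fractional overlap between consecutive segments.
#' @param frac required fraction of in-state samples.
#' @return tibble with `segment`, `start_s`, `end_s`, `state`.
#' @export
label_segments <- function(speed_cm_s, sampling_rate_hz = 2000, seg_s = 1,
                           overlap = 0.5, frac = 0.9) {
  step_s <- seg_s * (1 - overlap)
  n_samp <- length(speed_cm_s)
  duration_s <- n_samp / sampling_rate_hz
  starts <- seq(0, duration_s - seg_s, by = step_s)
  seg_len <- as.integer(round(seg_s * sampling_rate_hz))
  purrr::map_dfr(seq_along(starts), function(k) {
    i0 <- as.integer(round(starts[k] * sampling_rate_hz)) + 1L
    sp <- speed_cm_s[i0:(i0 + seg_len - 1L)]
    state <- if (mean(sp < 1) > frac) "immobility"
             else if (mean(sp > 3) > frac) "locomotion"
             else "excluded"
    tibble::tibble(segment = k, start_s = starts[k],
                   end_s = starts[k] + seg_s, state = state)
  })
}

#' Synchrony-triggered subthreshold voltage
#'
#' Extracts +/-`halfwidth_s` subVm segments around each synchrony event,
#' discards any segment in which the cell fired a spike, and averages the
#' survivors per cell; the grand mean averages across cells with at least one
#' surviving segment.
#'
#' @param subvms named list of per-cell subVm series.
#' @param spike_trains named list of the same cells' spike times (s).
#' @param event_times synchrony event times (s).
#' @param sampling_rate_hz imaging rate (Hz).
#' @param halfwidth_s window halfwidth (s).
#' @return list with `per_cell` (tibble `cell_id`, `n_segments`, list-column
#'   `mean_trace`), `grand_mean`, `lag_s`, `omitted` (cell ids with no
#'   surviving segment).
#' @export
synchrony_triggered_subvm <- function(subvms, spike_trains, event_times,
                                      sampling_rate_hz = 2000,
                                      halfwidth_s = 0.3) {
  stopifnot(length(event_times) >= 1)
  hw <- as.integer(round(halfwidth_s * sampling_rate_hz))
  lag_s <- seq(-hw, hw) / sampling_rate_hz
  ids <- names(subvms) %||% as.character(seq_along(subvms))
  per <- list()
  omitted <- character(0)
  for (ci in seq_along(subvms)) {
    sv <- subvms[[ci]]
    st <- spike_trains[[ci]]
    i0 <- align_indices(event_times, sampling_rate_hz) + 1L
    ok <- i0 - hw >= 1 & i0 + hw <= length(sv)
    segs <- list()
    for (i in i0[ok]) {
      t0 <- (i - 1L - hw) / sampling_rate_hz
      t1 <- (i - 1L + hw + 1L) / sampling_rate_hz
      if (any(st >= t0 & st < t1)) next  # spike inside window: discard
      segs[[length(segs) + 1L]] <- sv[(i - hw):(i + hw)]
    }
    if (length(segs) == 0) {
      omitted <- c(omitted, ids[ci])
      next
    }
    per[[length(per) + 1L]] <- tibble::tibble(
      cell_id = ids[ci], n_segments = length(segs),
      mean_trace = list(colMeans(do.call(rbind, segs))))
  }
  per_cell <- if (length(per) > 0) dplyr::bind_rows(per) else
    tibble::tibble(cell_id = character(0), n_segments = integer(0),
                   mean_trace = list())
  grand <- if (nrow(per_cell) > 0) {
    colMeans(do.call(rbind, per_cell$mean_trace))
  } else {
    rep(NA_real_, 2L * hw + 1L)
  }
  list(per_cell = per_cell, grand_mean = grand, lag_s = lag_s,
       omitted = omitted)
}

#' Phase modulation of spikes by intracellular theta, per category
#'
#' For each spike category (e.g. in/out of immobility or locomotion
#' synchrony) computes the amplitude-weighted vector strength and preferred
#' phase against the cell's own subVm theta phase, with uniform-redraw
#' shuffle significance restricted to the category's state intervals.
#'
#' @param categories named list of spike-time vectors (one per category).
#' @param ps the cell's subVm `phase_series` (theta band).
#' @param n_shuffles shuffles per category.
#' @param seed RNG seed.
#' @param shuffle_intervals optional named list of interval tibbles matching
#'   `categories`; shuffled spike times are drawn within them.
#' @return tibble `category`, `n_spikes`, `strength`, `preferred_phase`,
#'   `p_value` (categories with zero spikes are skipped).
#' @export
spike_phase_modulation <- function(categories, ps, n_shuffles = 1000,
                                   seed = 1, shuffle_intervals = NULL) {
  purrr::imap_dfr(categories, function(st, nm) {
    if (length(st) == 0) return(NULL)
    iv <- if (!is.null(shuffle_intervals)) shuffle_intervals[[nm]] else NULL
    m <- event_phase_modulation(st, ps, n_shuffles,
                                seed = derive_seed(seed, match(nm, names(categories))),
                                shuffle_intervals = iv)
    tibble::tibble(category = nm, n_spikes = length(st),
                   strength = m$strength, preferred_phase = m$preferred_phase,
                   p_value = m$p_value)
  })
}

#' Spike-triggered subVm averages per spike category
#'
#' @param subvm the cell's subVm series.
#' @param spike_times_by_category named list of spike-time vectors.
#' @param sampling_rate_hz imaging rate (Hz).
#' @param halfwidth_s window halfwidth (s).
#' @param min_triggers categories with fewer triggers are excluded.
#' @return tibble `category`, `n_triggers`, list-column `mean_trace`; the
#'   `lag_s` grid is attached as an attribute.
#' @export
spike_triggered_subvm <- function(subvm, spike_times_by_category,
                                  sampling_rate_hz = 2000, halfwidth_s = 0.3,
                                  min_triggers = 5) {
  hw <- as.integer(round(halfwidth_s * sampling_rate_hz))
  rows <- purrr::imap(spike_times_by_category, function(st, nm) {
    i0 <- align_indices(st, sampling_rate_hz) + 1L
    i0 <- i0[i0 - hw >= 1 & i0 + hw <= length(subvm)]
    if (length(i0) < min_triggers) return(NULL)
    seg <- t(vapply(i0, function(i) subvm[(i - hw):(i + hw)],
                    numeric(2L * hw + 1L)))
    tibble::tibble(category = nm, n_triggers = length(i0),
                   mean_trace = list(colMeans(seg)))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stop("all categories excluded (too few triggers)", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  attr(out, "lag_s") <- seq(-hw, hw) / sampling_rate_hz
  out
}

# z-scored cross-correlation of two equal-length segments at +/-max_lag
# samples; positive lag means b lags a. Normalized by (n - 1) to match the
# z-scoring, so the autocorrelation peaks at exactly 1.
segment_xcorr <- function(a, b, max_lag) {
  n <- length(a)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NULL)
  a <- (a - mean(a)) / sa
  b <- (b - mean(b)) / sb
  vapply(seq(-max_lag, max_lag), function(l) {
    if (l >= 0) sum(a[1:(n - l)] * b[(1 + l):n]) / (n - 1)
    else sum(a[(1 - l):n] * b[1:(n + l)]) / (n - 1)
  }, numeric(1))
}

#' Pairwise subVm cross-correlation by behavioral state
#'
#' For every co-occurring labeled segment (same start time; traces are
#' simultaneous) computes the z-scored cross-correlation at lags up to
#' +/-0.5 s and averages over segments of the same state. Positive lag means
#' cell b lags cell a.
#'
#' @param subvm_a,subvm_b subVm series of the two cells.
#' @param segments segment tibble from [label_segments()].
#' @param sampling_rate_hz imaging rate (Hz).
#' @param max_lag_s maximum lag (s).
#' @return tibble `state`, `n_segments`, list-columns `xcorr` and attribute
#'   `lag_s`; plus `peak` and `peak_lag_ms` per state.
#' @export
pairwise_subvm_xcorr <- function(subvm_a, subvm_b, segments,
                                 sampling_rate_hz = 2000, max_lag_s = 0.5) {
  max_lag <- as.integer(round(max_lag_s * sampling_rate_hz))
  lag_s <- seq(-max_lag, max_lag) / sampling_rate_hz
  out <- purrr::map_dfr(c("immobility", "locomotion"), function(s) {
    seg <- dplyr::filter(segments, .data$state == s)
    if (nrow(seg) == 0) return(NULL)
    xs <- list()
    for (k in seq_len(nrow(seg))) {
      i0 <- as.integer(round(seg$start_s[k] * sampling_rate_hz)) + 1L
      i1 <- as.integer(round(seg$end_s[k] * sampling_rate_hz))
      x <- segment_xcorr(subvm_a[i0:i1], subvm_b[i0:i1], max_lag)
      if (!is.null(x)) xs[[length(xs) + 1L]] <- x
    }
    if (length(xs) == 0) return(NULL)
    m <- colMeans(do.call(rbind, xs))
    pk <- which.max(m)
    tibble::tibble(state = s, n_segments = length(xs), xcorr = list(m),
                   peak = m[pk], peak_lag_ms = lag_s[pk] * 1000)
  })
  attr(out, "lag_s") <- lag_s
  out
}

# Welch cross-spectral estimate within one segment pair: Hann windows of
# `win` samples, 50% overlap. Returns freq grid and Sxx, Syy, Sxy sums.
welch_cross <- function(a, b, fs, win) {
  starts <- seq(1L, length(a) - win + 1L, by = win %/% 2L)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1L) / (win - 1L))
  half <- win %/% 2L + 1L
  sxx <- numeric(half); syy <- numeric(half); sxy <- complex(half)
  for (s in starts) {
    xa <- (a[s:(s + win - 1L)] - mean(a[s:(s + win - 1L)])) * h
    xb <- (b[s:(s + win - 1L)] - mean(b[s:(s + win - 1L)])) * h
    fa <- stats::fft(xa)[seq_len(half)]
    fb <- stats::fft(xb)[seq_len(half)]
    sxx <- sxx + Mod(fa)^2
    syy <- syy + Mod(fb)^2
    sxy <- sxy + fa * Conj(fb)
  }
  list(freq = fs * (seq_len(half) - 1L) / win, sxx = sxx, syy = syy, sxy = sxy,
       n_win = length(starts))
}

#' Pairwise subVm theta coherence by behavioral state
#'
#' Magnitude-squared coherence per co-occurring 1 s segment pair, estimated
#' by Welch's method inside the segment (0.5 s Hann windows, 50% overlap; a
#' single-window estimate is degenerate at 1), averaged over the theta band
#' (4-12 Hz) and then over same-state segments.
#'
#' @inheritParams pairwise_subvm_xcorr
#' @param theta_hz theta band.
#' @return tibble `state`, `n_segments`, `theta_coherence`, `low_confidence`
#'   (TRUE when fewer than 2 segments contributed).
#' @export
pairwise_theta_coherence <- function(subvm_a, subvm_b, segments,
                                     sampling_rate_hz = 2000,
                                     theta_hz = c(4, 12)) {
  purrr::map_dfr(c("immobility", "locomotion"), function(s) {
    seg <- dplyr::filter(segments, .data$state == s)
    if (nrow(seg) == 0) return(NULL)
    vals <- numeric(0)
    for (k in seq_len(nrow(seg))) {
      i0 <- as.integer(round(seg$start_s[k] * sampling_rate_hz)) + 1L
      i1 <- as.integer(round(seg$end_s[k] * sampling_rate_hz))
      a <- subvm_a[i0:i1]; b <- subvm_b[i0:i1]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      win <- as.integer(round(0.5 * sampling_rate_hz))
      w <- welch_cross(a, b, sampling_rate_hz, win)
      coh <- Mod(w$sxy)^2 / (w$sxx * w$syy)
      sel <- w$freq >= theta_hz[1] & w$freq <= theta_hz[2]
      vals <- c(vals, mean(coh[sel]))
    }
    if (length(vals) == 0) return(NULL)
    tibble::tibble(state = s, n_segments = length(vals),
                   theta_coherence = mean(vals),
                   low_confidence = length(vals) < 2)
  })
}

#' Spearman correlation between pair coherence and soma distance
#'
#' @param pair_coherences numeric theta coherences per cell pair.
#' @param centroid_distances_um soma distances per pair (um).
#' @return list with `rho` and `p_value` (Spearman).
#' @export
coherence_vs_distance <- function(pair_coherences, centroid_distances_um) {
  stopifnot(length(pair_coherences) == length(centroid_distances_um),
            length(pair_coherences) >= 3)
  if (stats::sd(pair_coherences) == 0 || stats::sd(centroid_distances_um) == 0) {
    stop("undefined correlation: ties-only input", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(pair_coherences, centroid_distances_um,
                    method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
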
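#' Baseline-corrected dF/F from raw fluorescence
#'
#' The baseline `F0(t)` is the moving average of the raw trace within
#' +/-`baseline_halfwidth_s` around each time point (windows truncated at the
#' edges), which removes slow bleaching. The sensor is negative-going, so dF/F
#' is computed as `(F0 - F) / F0`: spikes and depolarizations come out
#' positive.
#'
#' @param raw_f raw fluorescence vector (a.u.), strictly positive.
#' @param sampling_rate_hz imaging rate in Hz.
#' @param baseline_halfwidth_s halfwidth of the baseline window in seconds.
#' @return numeric dF/F vector.
#' @export
compute_dff <- function(raw_f, sampling_rate_hz = 2000,
                        baseline_halfwidth_s = 0.5) {
  hw <- as.integer(round(baseline_halfwidth_s * sampling_rate_hz))
  if (length(raw_f) <= 2 * hw) {
    stop("trace shorter than twice the baseline window", call. = FALSE)
  }
  f0 <- moving_average(raw_f, hw)
  if (any(f0 <= 0)) stop("degenerate baseline: nonpositive F0", call. = FALSE)
  (f0 - raw_f) / f0
}

#' High-passed residual of a dF/F trace
#'
#' Subtracts a running-median–filtered copy (5 ms window by default) from the
#' dF/F trace, leaving the fast spike transients. Edge windows shrink.
#'
#' @param dff dF/F vector.
#' @param sampling_rate_hz imaging rate in Hz.
#' @param median_window_ms median-filter window in milliseconds.
#' @return residual vector, same length as `dff`.
#' @export
highpass_residual <- function(dff, sampling_rate_hz = 2000,
                              median_window_ms = 5) {
  w <- median_window_ms / 1000 * sampling_rate_hz
  k <- 2L * floor(w / 2) + 1L   # odd sample count covering the window
  if (k < 3L) stop("median window shorter than 3 samples", call. = FALSE)
  dff - stats::runmed(dff, k, endrule = "med")
}

# Indices of strict local maxima (greater than both neighbours).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

#' Detect spikes in a high-passed residual trace
#'
#' Candidate transients are local maxima of the residual; the noise amplitude
#' distribution is formed from local maxima of the inverted residual. The
#' detection threshold minimizes the estimated sum of type I and type II
#' errors between the two empirical amplitude distributions: for each
#' candidate threshold the total error is (fraction of noise maxima >=
#' threshold) + (fraction of candidates < threshold); ties take the smallest
#' threshold. Events above threshold whose amplitude falls below half the mean
#' of the top 5% of kept amplitudes are then discarded. Peak times are refined
#' to sub-sample precision by parabolic interpolation over three samples.
#'
#' @param residual high-passed dF/F residual from [highpass_residual()].
#' @param sampling_rate_hz imaging rate in Hz.
#' @return list with `spike_times` (s), `spike_amplitudes`,
#'   `detection_threshold`.
#' @export
detect_spikes <- function(residual, sampling_rate_hz = 2000) {
  if (length(residual) < sampling_rate_hz) {
    stop("need at least 1 s of residual", call. = FALSE)
  }
  if (stats::sd(residual) == 0) {
    stop("degenerate noise: zero-variance residual", call. = FALSE)
  }
  cand_idx <- local_maxima(residual)
  if (length(cand_idx) == 0) {
    return(list(spike_times = numeric(0), spike_amplitudes = numeric(0),
                detection_threshold = NA_real_))
  }
  cand_amp <- residual[cand_idx]
  noise_amp <- (-residual)[local_maxima(-residual)]

  grid <- sort(unique(c(cand_amp, noise_amp)))
  # counts via sorted search: noise maxima >= theta, candidates < theta
  n_noise_ge <- length(noise_amp) -
    findInterval(grid, sort(noise_amp), left.open = TRUE)
  n_cand_lt <- findInterval(grid, sort(cand_amp), left.open = TRUE)
  total_err <- n_noise_ge / max(length(noise_amp), 1L) +
    n_cand_lt / length(cand_amp)
  theta <- grid[which.min(total_err)]   # which.min takes the first (smallest)

  keep <- cand_amp >= theta
  idx <- cand_idx[keep]
  amp <- cand_amp[keep]
  if (length(amp) > 0) {
    top <- sort(amp, decreasing = TRUE)
    n_top <- max(1L, ceiling(0.05 * length(top)))
    amp_floor <- 0.5 * mean(top[seq_len(n_top)])
    keep2 <- amp >= amp_floor
    idx <- idx[keep2]
    amp <- amp[keep2]
  }
  # parabolic refinement of peak time and amplitude
  if (length(idx) > 0) {
    y0 <- residual[idx - 1L]; y1 <- residual[idx]; y2 <- residual[idx + 1L]
    denom <- (y0 - 2 * y1 + y2)
    delta <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
    delta <- pmax(pmin(delta, 0.5), -0.5)
    t_spk <- (idx - 1L + delta) / sampling_rate_hz
    amp_ref <- y1 - 0.25 * (y0 - y2) * delta
    ord <- order(t_spk)
    t_spk <- t_spk[ord]; amp_ref <- amp_ref[ord]
  } else {
    t_spk <- numeric(0); amp_ref <- numeric(0)
  }
  list(spike_times = t_spk, spike_amplitudes = amp_ref,
       detection_threshold = theta)
}

#' Spike signal-to-noise ratio
#'
#' Mean spike amplitude divided by the SD of the residual after deleting the
#' samples from 2 ms before to 4 ms after every spike.
#'
#' @param residual high-passed residual.
#' @param spike_times spike times in seconds.
#' @param spike_amplitudes spike amplitudes; defaults to residual at spikes.
#' @param sampling_rate_hz imaging rate in Hz.
#' @return numeric SNR.
#' @export
compute_snr <- function(residual, spike_times, spike_amplitudes = NULL,
                        sampling_rate_hz = 2000) {
  if (length(spike_times) == 0) {
    stop("SNR undefined without spikes", call. = FALSE)
  }
  if (is.null(spike_amplitudes)) {
    spike_amplitudes <-
      residual[pmin(align_indices(spike_times, sampling_rate_hz) + 1L,
                    length(residual))]
  }
  drop <- rep(FALSE, length(residual))
  i0 <- align_indices(spike_times, sampling_rate_hz) + 1L
  lo <- pmax(i0 - as.integer(round(0.002 * sampling_rate_hz)), 1L)
  hi <- pmin(i0 + as.integer(round(0.004 * sampling_rate_hz)), length(residual))
  for (k in seq_along(i0)) drop[lo[k]:hi[k]] <- TRUE
  noise_sd <- stats::sd(residual[!drop])
  mean(spike_amplitudes) / noise_sd
}

# FWHM (ms) of the spike-triggered mean residual waveform in a +/-5 ms window;
# linear interpolation between samples at the half-max crossings.
spike_waveform_fwhm <- function(residual, spike_times, sampling_rate_hz = 2000) {
  hw <- as.integer(round(0.005 * sampling_rate_hz))
  i0 <- align_indices(spike_times, sampling_rate_hz) + 1L
  ok <- i0 - hw >= 1 & i0 + hw <= length(residual)
  i0 <- i0[ok]
  if (length(i0) == 0) return(NA_real_)
  seg <- vapply(i0, function(i) residual[(i - hw):(i + hw)],
                numeric(2L * hw + 1L))
  wf <- rowMeans(seg)
  peak_i <- which.max(wf)
  half <- wf[peak_i] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(peak_i, 2L)) {
    if (wf[i - 1L] <= half) {
      left <- (i - 1L) + (half - wf[i - 1L]) / (wf[i] - wf[i - 1L])
      break
    }
  }
  for (i in seq(peak_i, length(wf) - 1L)) {
    if (wf[i + 1L] <= half) {
      right <- i + (wf[i] - half) / (wf[i] - wf[i + 1L])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / sampling_rate_hz * 1000
}

#' Extract the subthreshold membrane-voltage proxy
#'
#' The slow trace is `dff - residual`. The spike threshold is the value of the
#' mean spike waveform (spike-triggered dF/F average, +/-5 ms) at the time of
#' the peak of its first derivative; slow-trace samples above that threshold
#' are replaced by linear interpolation between the nearest flanking
#' sub-threshold samples (nearest-value extension at trace boundaries).
#'
#' @param dff dF/F trace.
#' @param residual high-passed residual.
#' @param spike_times spike times (s); with no spikes the slow trace is
#'   returned unchanged.
#' @param sampling_rate_hz imaging rate in Hz.
#' @return list with `subvm` and `spike_threshold_v`.
#' @export
extract_subvm <- function(dff, residual, spike_times,
                          sampling_rate_hz = 2000) {
  slow <- dff - residual
  if (length(spike_times) == 0) {
    return(list(subvm = slow, spike_threshold_v = NA_real_))
  }
  hw <- as.integer(round(0.005 * sampling_rate_hz))
  i0 <- align_indices(spike_times, sampling_rate_hz) + 1L
  ok <- i0 - hw >= 1 & i0 + hw <= length(dff)
  wf <- if (any(ok)) {
    rowMeans(vapply(i0[ok], function(i) dff[(i - hw):(i + hw)],
                    numeric(2L * hw + 1L)))
  } else {
    dff[max(i0[1] - hw, 1):min(i0[1] + hw, length(dff))]
  }
  d1 <- diff(wf)
  thr <- wf[which.max(d1)]   # value at the steepest rising point
  above <- slow > thr
  if (all(above)) {
    warning("degenerate subvm: entire trace above spike threshold")
    return(list(subvm = rep(thr, length(slow)), spike_threshold_v = thr))
  }
  if (any(above)) {
    runs <- logical_runs(above)
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1]; b <- runs[r, 2]
      if (a == 1L && b == length(slow)) next
      if (a == 1L) {
        slow[a:b] <- slow[b + 1L]
      } else if (b == length(slow)) {
        slow[a:b] <- slow[a - 1L]
      } else {
        slow[a:b] <- slow[a - 1L] +
          (slow[b + 1L] - slow[a - 1L]) * seq_len(b - a + 1L) / (b - a + 2L)
      }
    }
  }
  list(subvm = slow, spike_threshold_v = thr)
}

#' Full per-cell preprocessing
#'
#' Runs [compute_dff()], [highpass_residual()], [detect_spikes()],
#' [compute_snr()] and [extract_subvm()] on one raw fluorescence trace.
#'
#' @param raw_f raw fluorescence vector.
#' @param sampling_rate_hz imaging rate in Hz.
#' @param cell_id optional id carried through.
#' @return A `cell_activity` list: `dff`, `hp_residual`, `spike_times`,
#'   `spike_amplitudes`, `detection_threshold`, `spike_threshold_v`, `snr`,
#'   `subvm`, `mean_rate_hz`, `fwhm_ms`.
#' @export
process_cell <- function(raw_f, sampling_rate_hz = 2000, cell_id = NA_character_) {
  dff <- compute_dff(raw_f, sampling_rate_hz)
  res <- highpass_residual(dff, sampling_rate_hz)
  det <- detect_spikes(res, sampling_rate_hz)
  duration_s <- length(raw_f) / sampling_rate_hz
  snr <- if (length(det$spike_times) > 0) {
    compute_snr(res, det$spike_times, det$spike_amplitudes, sampling_rate_hz)
  } else {
    NA_real_
  }
  sv <- extract_subvm(dff, res, det$spike_times, sampling_rate_hz)
  fwhm <- if (length(det$spike_times) > 0) {
    spike_waveform_fwhm(res, det$spike_times, sampling_rate_hz)
  } else {
    NA_real_
  }
  structure(
    list(cell_id = cell_id, dff = dff, hp_residual = res,
         spike_times = det$spike_times,
         spike_amplitudes = det$spike_amplitudes,
         detection_threshold = det$detection_threshold,
         spike_threshold_v = sv$spike_threshold_v,
         snr = snr, subvm = sv$subvm,
         mean_rate_hz = length(det$spike_times) / duration_s,
         fwhm_ms = fwhm,
         sampling_rate_hz = sampling_rate_hz),
    class = "cell_activity"
  )
}

#' Quality-control cell selection
#'
#' Keeps cells with SNR > 5, spike-waveform FWHM > 0.8 ms and mean rate
#' > 0.1 Hz, then greedily drops the lower-SNR member of any centroid pair
#' closer than 70 um. The session is analyzable only if at least 9 cells
#' survive.
#'
#' @param activities list of `cell_activity` objects from [process_cell()].
#' @param centroids matrix (n x 2) of ROI centroids in micrometers.
#' @param min_snr,min_fwhm_ms,min_rate_hz,min_dist_um,min_cells QC thresholds.
#' @return list with `report` (tibble: per-cell metrics and flags), `included`
#'   (character ids), `analyzable` (logical).
#' @export
qc_cells <- function(activities, centroids, min_snr = 5, min_fwhm_ms = 0.8,
                     min_rate_hz = 0.1, min_dist_um = 70, min_cells = 9) {
  stopifnot(length(activities) > 0)
  centroids <- as.matrix(centroids)
  ids <- vapply(seq_along(activities),
                function(i) activities[[i]]$cell_id %||% as.character(i),
                character(1))
  snr <- vapply(activities, function(a) a$snr %||% NA_real_, numeric(1))
  fwhm <- vapply(activities, function(a) a$fwhm_ms %||% NA_real_, numeric(1))
  rate <- vapply(activities, function(a) a$mean_rate_hz, numeric(1))
  pass1 <- !is.na(snr) & snr > min_snr &
    !is.na(fwhm) & fwhm > min_fwhm_ms & rate > min_rate_hz

  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  alive <- pass1
  repeat {
    dd <- d
    dd[!alive, ] <- Inf
    dd[, !alive] <- Inf
    m <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    if (!is.finite(dd[m[1], m[2]]) || dd[m[1], m[2]] >= min_dist_um) break
    drop_i <- if (snr[m[1]] <= snr[m[2]]) m[1] else m[2]
    alive[drop_i] <- FALSE
  }
  min_pair <- apply(d, 1, min)
  report <- tibble::tibble(
    cell_id = ids, snr = snr, fwhm_ms = fwhm, mean_rate_hz = rate,
    min_pair_dist_um = min_pair,
    qc_pass = alive
  )
  list(report = report, included = ids[alive],
       analyzable = sum(alive) >= min_cells)
}

#' Preprocess every cell in a session bundle
#'
#' @param bundle a `session_bundle`.
#' @return list with `activities` (named list of `cell_activity`), `qc`
#'   (from [qc_cells()]), `spikes` (tibble `cell_id`, `spike_time_s`,
#'   `amplitude` over QC-passing cells).
#' @export
preprocess_session <- function(bundle) {
  activities <- lapply(bundle$cells, function(cc) {
    process_cell(cc$raw_f, cc$sampling_rate_hz, cc$cell_id)
  })
  names(activities) <- vapply(bundle$cells, function(cc) cc$cell_id, character(1))
  centroids <- do.call(rbind, lapply(bundle$cells, function(cc) cc$centroid_xy))
  qc <- qc_cells(activities, centroids)
  spikes <- purrr::map_dfr(activities[qc$included], function(a) {
    tibble::tibble(cell_id = a$cell_id, spike_time_s = a$spike_times,
                   amplitude = a$spike_amplitudes)
  })
  list(activities = activities, qc = qc, spikes = spikes)
}
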
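#' Population spike counts in a sliding window
#'
#' Total spikes across all cells inside `[t - w/2, t + w/2)` evaluated at
#' every imaging sample (step = 1 sample).
#'
#' @param spike_trains list of per-cell spike-time vectors (seconds).
#' @param duration_s session duration in seconds.
#' @param sampling_rate_hz imaging rate in Hz.
#' @param window_ms sliding-window width in milliseconds.
#' @return numeric vector of counts, one per imaging sample.
#' @export
sliding_counts <- function(spike_trains, duration_s,
                           sampling_rate_hz = 2000, window_ms = 25) {
  stopifnot(length(spike_trains) >= 1)
  n <- as.integer(round(duration_s * sampling_rate_hz))
  all_spikes <- unlist(spike_trains, use.names = FALSE)
  binned <- numeric(n)
  if (length(all_spikes) > 0) {
    bin <- floor(all_spikes * sampling_rate_hz) + 1L  # sample i covers [i/fs,(i+1)/fs)
    bin <- bin[bin >= 1 & bin <= n]
    tb <- tabulate(bin, nbins = n)
    binned <- as.numeric(tb)
  }
  half <- as.integer(round(window_ms / 1000 * sampling_rate_hz / 2))
  # window [t - w/2, t + w/2) with t = i/fs covers sample bins i-half .. i+half-1
  rolling_sum(binned, before = half, after = half - 1L)
}

#' Surrogate sliding counts from spike-time jittering
#'
#' Each surrogate displaces every spike independently by a uniform offset on
#' +/-`halfwidth_ms` (clipped to the session bounds), preserving per-cell
#' spike counts, and recomputes the sliding counts. Returns the per-sample
#' mean and SD over surrogates.
#'
#' @param spike_trains list of per-cell spike-time vectors.
#' @param duration_s session duration (s).
#' @param sampling_rate_hz imaging rate (Hz).
#' @param window_ms sliding-window width (ms).
#' @param halfwidth_ms jitter halfwidth (ms).
#' @param n number of surrogates.
#' @param seed RNG seed (required for reproducibility).
#' @return list with `mean`, `sd` (per-sample), `n_jitters`,
#'   `jitter_halfwidth_ms`.
#' @export
jitter_surrogates <- function(spike_trains, duration_s,
                              sampling_rate_hz = 2000, window_ms = 25,
                              halfwidth_ms = 75, n = 500, seed) {
  stopifnot(n >= 2)
  hw <- halfwidth_ms / 1000
  n_samp <- as.integer(round(duration_s * sampling_rate_hz))
  all_spikes <- unlist(spike_trains, use.names = FALSE)
  if (length(all_spikes) == 0) {
    z <- numeric(n_samp)
    return(list(mean = z, sd = z, n_jitters = n,
                jitter_halfwidth_ms = halfwidth_ms))
  }
  half <- as.integer(round(window_ms / 1000 * sampling_rate_hz / 2))
  acc <- numeric(n_samp)
  acc2 <- numeric(n_samp)
  eps <- 1e-9
  with_seed(seed, {
    for (k in seq_len(n)) {
      jit <- all_spikes + stats::runif(length(all_spikes), -hw, hw)
      jit <- pmin(pmax(jit, 0), duration_s - eps)
      bin <- floor(jit * sampling_rate_hz) + 1L
      counts <- rolling_sum(as.numeric(tabulate(bin, nbins = n_samp)),
                            before = half, after = half - 1L)
      acc <- acc + counts
      acc2 <- acc2 + counts^2
    }
  })
  m <- acc / n
  v <- pmax((acc2 - n * m^2) / (n - 1), 0)
  list(mean = m, sd = sqrt(v), n_jitters = n,
       jitter_halfwidth_ms = halfwidth_ms)
}

#' Detect population-synchrony events against the surrogate threshold
#'
#' Samples where the observed count exceeds `surrogate mean + k_sd * SD` are
#' supra-threshold; contiguous runs merge into one event timestamped at the
#' run midpoint. Participants are the cells with at least one spike within
#' +/-`participant_halfwidth_ms` of the event time; the ensemble size is the
#' participant percentage of analyzable cells.
#'
#' @param counts observed sliding counts from [sliding_counts()].
#' @param surrogates result of [jitter_surrogates()].
#' @param spike_trains named list of per-cell spike-time vectors (the
#'   analyzable cells).
#' @param sampling_rate_hz imaging rate (Hz).
#' @param k_sd threshold in surrogate SDs above the surrogate mean.
#' @param window_ms sliding-window width (ms), recorded in the result.
#' @param participant_halfwidth_ms participant window halfwidth (ms).
#' @return A `sync_events` object: tibble `events` (`event_time_s`,
#'   `start_s`, `end_s`, `n_participants`, `ensemble_size_pct`, `peak_count`,
#'   `threshold_at_peak`), list-column `participants`, plus detection
#'   metadata.
#' @export
detect_events <- function(counts, surrogates, spike_trains,
                          sampling_rate_hz = 2000, k_sd = 4,
                          window_ms = 25, participant_halfwidth_ms = 12.5) {
  stopifnot(length(counts) == length(surrogates$mean))
  thr <- surrogates$mean + k_sd * surrogates$sd
  above <- counts > thr
  ids <- names(spike_trains) %||% as.character(seq_along(spike_trains))
  if (!any(above)) {
    ev <- tibble::tibble(event_time_s = numeric(0), start_s = numeric(0),
                         end_s = numeric(0), n_participants = integer(0),
                         ensemble_size_pct = numeric(0),
                         peak_count = numeric(0),
                         threshold_at_peak = numeric(0),
                         participants = list())
  } else {
    runs <- logical_runs(above)
    hw <- participant_halfwidth_ms / 1000
    rows <- lapply(seq_len(nrow(runs)), function(r) {
      a <- runs[r, 1]; b <- runs[r, 2]
      start_s <- (a - 1L) / sampling_rate_hz
      end_s <- b / sampling_rate_hz
      mid <- (start_s + end_s) / 2
      peak_i <- a - 1L + which.max(counts[a:b])
      part <- ids[vapply(spike_trains, function(st) {
        any(st >= mid - hw & st <= mid + hw)
      }, logical(1))]
      tibble::tibble(event_time_s = mid, start_s = start_s, end_s = end_s,
                     n_participants = length(part),
                     ensemble_size_pct = 100 * length(part) / length(spike_trains),
                     peak_count = counts[peak_i],
                     threshold_at_peak = thr[peak_i],
                     participants = list(part))
    })
    ev <- dplyr::bind_rows(rows)
  }
  structure(
    list(events = ev, n_cells = length(spike_trains),
         window_ms = window_ms, k_sd = k_sd,
         n_jitters = surrogates$n_jitters,
         jitter_halfwidth_ms = surrogates$jitter_halfwidth_ms,
         duration_s = length(counts) / sampling_rate_hz),
    class = "sync_events"
  )
}

#' @export
print.sync_events <- function(x, ...) {
  cat("<sync_events> ", nrow(x$events), " events over ", x$duration_s,
      " s (", signif(nrow(x$events) / x$duration_s, 3), " Hz), ",
      x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Detect synchrony in one call
#'
#' Convenience wrapper running [sliding_counts()], [jitter_surrogates()] and
#' [detect_events()] with the standard parameters.
#'
#' @inheritParams jitter_surrogates
#' @inheritParams detect_events
#' @param spike_trains named list of per-cell spike times.
#' @param n_jitters number of jitter surrogates.
#' @return A `sync_events` object.
#' @export
detect_synchrony <- function(spike_trains, duration_s,
                             sampling_rate_hz = 2000, window_ms = 25,
                             jitter_halfwidth_ms = 75, n_jitters = 500,
                             k_sd = 4, seed) {
  counts <- sliding_counts(spike_trains, duration_s, sampling_rate_hz,
                           window_ms)
  sur <- jitter_surrogates(spike_trains, duration_s, sampling_rate_hz,
                           window_ms, jitter_halfwidth_ms, n_jitters, seed)
  detect_events(counts, sur, spike_trains, sampling_rate_hz, k_sd, window_ms)
}

#' Synchronous-event rates in equal session segments
#'
#' @param events a `sync_events` object (or tibble with `event_time_s`).
#' @param duration_s session duration (s).
#' @param n_segments number of equal segments (halves by default).
#' @return tibble `segment`, `start_s`, `end_s`, `n_events`, `rate_hz`.
#' @export
event_rate_segments <- function(events, duration_s, n_segments = 2) {
  stopifnot(duration_s > 0)
  times <- if (inherits(events, "sync_events")) events$events$event_time_s
           else events$event_time_s
  breaks <- seq(0, duration_s, length.out = n_segments + 1)
  n <- vapply(seq_len(n_segments), function(k) {
    sum(times >= breaks[k] & times < breaks[k + 1]) +
      if (k == n_segments) sum(times == duration_s) else 0L
  }, numeric(1))
  tibble::tibble(segment = seq_len(n_segments),
                 start_s = breaks[-length(breaks)], end_s = breaks[-1],
                 n_events = as.integer(n),
                 rate_hz = n / diff(breaks))
}

#' Remove later spikes of bursts
#'
#' Keeps a spike iff it is the first of its train or its preceding inter-spike
#' interval exceeds `isi_max_ms` (burst-initiating spikes kept, followers
#' dropped).
#'
#' @param spike_times sorted spike times (s).
#' @param isi_max_ms maximal intra-burst inter-spike interval (ms).
#' @return filtered spike times.
#' @export
remove_burst_spikes <- function(spike_times, isi_max_ms = 10) {
  if (length(spike_times) <= 1) return(spike_times)
  keep <- logical(length(spike_times))
  keep[1] <- TRUE
  last_kept <- spike_times[1]
  for (i in 2:length(spike_times)) {
    if (spike_times[i] - spike_times[i - 1] > isi_max_ms / 1000) {
      keep[i] <- TRUE
    }
  }
  spike_times[keep]
}

#' Shuffle spikes across theta cycles, preserving phase
#'
#' Cycles are delimited by ascending zero crossings of the wrapped theta
#' phase (phase 0 = oscillation peak). Each spike keeps its phase but is
#' re-placed in a uniformly redrawn cycle (with replacement); the new time is
#' found by linear interpolation of the unwrapped phase within the new cycle.
#' Cycles whose phase is non-monotone after unwrapping are excluded from the
#' draw.
#'
#' @param spike_times sorted spike times (s) of one cell.
#' @param theta_phase radians per LFP/imaging sample, in (-pi, pi].
#' @param sampling_rate_hz rate of the phase series.
#' @param seed RNG seed.
#' @return shuffled, sorted spike times.
#' @export
theta_cycle_shuffle <- function(spike_times, theta_phase,
                                sampling_rate_hz = 2000, seed) {
  if (length(spike_times) == 0) return(spike_times)
  # ascending zero crossings of wrapped phase: previous sample < 0, this >= 0,
  # excluding the -pi/pi wrap itself
  ph <- theta_phase
  n <- length(ph)
  cross <- which(ph[-1] >= 0 & ph[-n] < 0 & (ph[-1] - ph[-n]) < pi) + 1L
  if (length(cross) < 2) return(sort(spike_times))  # single cycle: identity
  cyc_start <- cross[-length(cross)]
  cyc_end <- cross[-1]  # exclusive
  n_cyc <- length(cyc_start)

  # per-cycle unwrapped phase (0..2pi); exclude non-monotone cycles
  unwrap_cycle <- function(k) {
    seg <- ph[cyc_start[k]:(cyc_end[k])]
    jumps <- c(0, cumsum(diff(seg) < -pi))
    seg + 2 * pi * jumps
  }
  mono <- vapply(seq_len(n_cyc), function(k) {
    u <- unwrap_cycle(k); all(diff(u) > 0)
  }, logical(1))
  ok_cycles <- which(mono)
  if (length(ok_cycles) == 0) return(sort(spike_times))

  spike_idx <- align_indices(spike_times, sampling_rate_hz) + 1L
  spike_idx <- pmin(pmax(spike_idx, 1L), n)
  spike_cycle <- findInterval(spike_idx, cyc_start)
  in_cov <- spike_cycle >= 1 & spike_idx < cyc_end[pmax(spike_cycle, 1L)]

  out <- spike_times
  with_seed(seed, {
    for (i in which(in_cov)) {
      phi <- ph[spike_idx[i]]
      if (phi < 0) phi <- phi + 2 * pi
      k_new <- ok_cycles[sample.int(length(ok_cycles), 1L)]
      u <- unwrap_cycle(k_new)
      tt <- (cyc_start[k_new]:(cyc_end[k_new]) - 1L) / sampling_rate_hz
      phi <- min(max(phi, u[1]), u[length(u)])
      out[i] <- stats::approx(u, tt, xout = phi, ties = "ordered")$y
    }
  })
  sort(out)
}
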
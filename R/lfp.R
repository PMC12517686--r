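#' Detect ripple oscillations in an LFP trace
#'
#' Band-passes the LFP (120-240 Hz, zero-phase 4th-order Butterworth), takes
#' the Hilbert envelope, low-passes it at 20 Hz, and finds maximal runs above
#' `mean + 3.5 SD` of the envelope that contain at least one sample above
#' `mean + 7 SD` and last at least 30 ms. Start/end are the lower-threshold
#' crossings; the event peak is the envelope maximum. Envelope statistics are
#' computed over the whole trace.
#'
#' @param lfp numeric LFP samples or an `lfp_trace`.
#' @param sampling_rate_hz LFP rate (ignored when `lfp` is an `lfp_trace`).
#' @param band_hz ripple band.
#' @param k_low,k_high lower/upper thresholds in envelope SDs above the mean.
#' @param min_duration_ms minimum event duration.
#' @return tibble with `start_s`, `end_s`, `peak_s`, `peak_power`,
#'   `duration_ms`.
#' @export
detect_ripples <- function(lfp, sampling_rate_hz = 8000,
                           band_hz = c(120, 240), k_low = 3.5, k_high = 7,
                           min_duration_ms = 30) {
  if (inherits(lfp, "lfp_trace")) {
    sampling_rate_hz <- lfp$sampling_rate_hz
    lfp <- lfp$samples
  }
  stopifnot(length(lfp) >= sampling_rate_hz)
  if (stats::sd(lfp) == 0) stop("degenerate signal: constant LFP", call. = FALSE)
  bp <- bandpass_filtfilt(lfp, band_hz, sampling_rate_hz, order = 4)
  env <- Mod(analytic_signal(bp))
  env <- lowpass_filtfilt(env, 20, sampling_rate_hz, order = 2)
  mu <- mean(env); s <- stats::sd(env)
  lower <- mu + k_low * s
  upper <- mu + k_high * s
  runs <- logical_runs(env > lower)
  out <- list()
  edge <- as.integer(round(0.1 * sampling_rate_hz))  # filter-transient margin
  if (length(runs) > 0) {
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1]; b <- runs[r, 2]
      if (a <= edge || b >= length(env) - edge) next
      dur_ms <- (b - a + 1L) / sampling_rate_hz * 1000
      if (dur_ms < min_duration_ms) next
      seg <- env[a:b]
      if (max(seg) < upper) next
      peak_i <- a - 1L + which.max(seg)
      out[[length(out) + 1L]] <- tibble::tibble(
        start_s = (a - 1L) / sampling_rate_hz,
        end_s = b / sampling_rate_hz,
        peak_s = (peak_i - 1L) / sampling_rate_hz,
        peak_power = max(seg),
        duration_ms = dur_ms
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                   peak_s = numeric(0), peak_power = numeric(0),
                   duration_ms = numeric(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' Ripple modulation index of a spike train
#'
#' `(r_in - r_out) / (r_in + r_out)` with `r_in`/`r_out` the mean firing
#' rates inside/outside the ripple intervals. Significance comes from
#' circularly time-shifting the whole spike train by a uniform offset
#' (preserving ISI structure) `n_shuffles` times; `p` is the two-sided tail
#' fraction of shuffled indices at least as extreme as the observed one.
#'
#' @param spike_times spike times (s).
#' @param ripples tibble with `start_s`, `end_s` (from [detect_ripples()]).
#' @param duration_s session duration (s).
#' @param n_shuffles number of circular shifts.
#' @param seed RNG seed.
#' @return list with `index`, `p_value`, `rate_in_hz`, `rate_out_hz`.
#' @export
ripple_modulation_index <- function(spike_times, ripples, duration_s,
                                    n_shuffles = 1000, seed = 1) {
  t_in <- interval_total(ripples[, c("start_s", "end_s")])
  stopifnot(t_in > 0)
  t_out <- duration_s - t_in
  mod_index <- function(st) {
    n_in <- sum(in_intervals(st, ripples[, c("start_s", "end_s")]))
    r_in <- n_in / t_in
    r_out <- (length(st) - n_in) / t_out
    if (r_in + r_out == 0) return(NA_real_)
    (r_in - r_out) / (r_in + r_out)
  }
  obs <- mod_index(spike_times)
  if (is.na(obs)) stop("undefined index: no spikes", call. = FALSE)
  shuf <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      mod_index((spike_times + stats::runif(1, 0, duration_s)) %% duration_s)
    }, numeric(1))
  })
  p <- mean(abs(shuf) >= abs(obs), na.rm = TRUE)
  list(index = obs, p_value = p,
       rate_in_hz = sum(in_intervals(spike_times,
                                     ripples[, c("start_s", "end_s")])) / t_in,
       rate_out_hz = (length(spike_times) -
                      sum(in_intervals(spike_times,
                                       ripples[, c("start_s", "end_s")]))) / t_out)
}

#' Co-occurrence between point events and intervals
#'
#' Direction 1: percentage of intervals containing at least one event.
#' Direction 2: percentage of events falling inside any interval.
#'
#' @param event_times event times (s).
#' @param intervals tibble with `start_s`, `end_s`.
#' @return list with `pct_intervals_with_event`, `pct_events_in_intervals`,
#'   `empty_input` flag.
#' @export
co_occurrence <- function(event_times, intervals) {
  empty <- length(event_times) == 0 || is.null(intervals) || nrow(intervals) == 0
  if (empty) {
    return(list(pct_intervals_with_event = 0, pct_events_in_intervals = 0,
                empty_input = TRUE))
  }
  hit_iv <- vapply(seq_len(nrow(intervals)), function(i) {
    any(event_times >= intervals$start_s[i] & event_times < intervals$end_s[i])
  }, logical(1))
  in_iv <- in_intervals(event_times, intervals[, c("start_s", "end_s")])
  list(pct_intervals_with_event = 100 * mean(hit_iv),
       pct_events_in_intervals = 100 * mean(in_iv),
       empty_input = FALSE)
}

#' Event-triggered average of a signal
#'
#' Extracts +/-`halfwidth_s` segments around each trigger; triggers too close
#' to an edge are dropped (their count is reported).
#'
#' @param signal numeric series.
#' @param trigger_times trigger times (s).
#' @param sampling_rate_hz rate of `signal`.
#' @param halfwidth_s segment halfwidth (s).
#' @return list with `mean` (trace), `segments` (trigger x sample matrix),
#'   `lag_s`, `n_used`, `n_dropped`.
#' @export
triggered_average <- function(signal, trigger_times, sampling_rate_hz,
                              halfwidth_s) {
  hw <- as.integer(round(halfwidth_s * sampling_rate_hz))
  i0 <- align_indices(trigger_times, sampling_rate_hz) + 1L
  ok <- i0 - hw >= 1 & i0 + hw <= length(signal)
  if (!any(ok)) stop("no valid trigger fully inside the recording", call. = FALSE)
  seg <- t(vapply(i0[ok], function(i) signal[(i - hw):(i + hw)],
                  numeric(2L * hw + 1L)))
  list(mean = colMeans(seg), segments = seg,
       lag_s = seq(-hw, hw) / sampling_rate_hz,
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' One-sided FFT power spectrum of a short trace
#'
#' Zero-pads the trace to `nfft` points; power is the squared modulus of the
#' Fourier coefficients on the one-sided frequency grid `fs * k / nfft`.
#'
#' @param trace numeric trace (length <= `nfft`).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param nfft FFT length.
#' @return tibble with `freq_hz`, `power`.
#' @export
psd_fft <- function(trace, sampling_rate_hz, nfft = 16384) {
  stopifnot(length(trace) <= nfft)
  x <- c(trace, numeric(nfft - length(trace)))
  co <- stats::fft(x)
  half <- nfft %/% 2 + 1L
  tibble::tibble(
    freq_hz = sampling_rate_hz * (seq_len(half) - 1L) / nfft,
    power = Mod(co[seq_len(half)])^2
  )
}

#' Summed power in the ripple band
#'
#' @param psd tibble from [psd_fft()].
#' @param band_hz frequency band (Hz), inclusive.
#' @return scalar power.
#' @export
ripple_band_power <- function(psd, band_hz = c(120, 240)) {
  stopifnot(max(psd$freq_hz) >= band_hz[2])
  sum(psd$power[psd$freq_hz >= band_hz[1] & psd$freq_hz <= band_hz[2]])
}

#' Instantaneous phase and amplitude of a band-limited component
#'
#' Zero-phase Butterworth band-pass followed by the Hilbert analytic signal.
#' Phase convention: 0 rad at the filtered-signal peak, +/-pi at the trough.
#'
#' @param x numeric series.
#' @param band_hz band `[low, high]` in Hz, inside `(0, fs/2)`.
#' @param sampling_rate_hz sampling rate.
#' @param order Butterworth order.
#' @return A `phase_series` list: `phi` (radians), `amp`, `band_hz`,
#'   `sampling_rate_hz`.
#' @export
phase_series <- function(x, band_hz, sampling_rate_hz, order = 4) {
  filt <- bandpass_filtfilt(x, band_hz, sampling_rate_hz, order)
  an <- analytic_signal(filt)
  structure(list(phi = Arg(an), amp = Mod(an), band_hz = band_hz,
                 sampling_rate_hz = sampling_rate_hz, filtered = filt),
            class = "phase_series")
}

# Phase/amplitude at event times (nearest sample).
phase_at <- function(ps, t) {
  i <- pmin(pmax(align_indices(t, ps$sampling_rate_hz) + 1L, 1L),
            length(ps$phi))
  list(phi = ps$phi[i], amp = ps$amp[i])
}

#' Amplitude-weighted phase modulation of point events
#'
#' Each event at time `t_k` contributes the vector `V_k = A(t_k) *
#' exp(i * phi(t_k))`. Modulation strength is `|sum V_k| / sum |V_k|`
#' (in `[0, 1]`); the preferred phase is `arg(sum V_k)`. Significance is the
#' fraction of `n_shuffles` uniform redraws of the event times whose strength
#' reaches the observed one.
#'
#' @param event_times event times (s).
#' @param ps a `phase_series`.
#' @param n_shuffles number of uniform time shuffles.
#' @param seed RNG seed.
#' @param shuffle_intervals optional tibble `start_s`,`end_s`: shuffled times
#'   are drawn uniformly from these intervals instead of the whole series.
#' @return list with `strength`, `preferred_phase` (radians), `p_value`,
#'   `n_events`.
#' @export
event_phase_modulation <- function(event_times, ps, n_shuffles = 1000,
                                   seed = 1, shuffle_intervals = NULL) {
  stopifnot(length(event_times) >= 1)
  duration <- length(ps$phi) / ps$sampling_rate_hz
  vstat <- function(t) {
    pa <- phase_at(ps, t)
    tot <- sum(pa$amp)
    if (tot == 0) return(c(NA_real_, NA_real_))
    v <- sum(pa$amp * exp(1i * pa$phi))
    c(Mod(v) / tot, Arg(v))
  }
  obs <- vstat(event_times)
  if (is.na(obs[1])) stop("undefined modulation: all amplitudes zero", call. = FALSE)
  draw <- function(n) {
    if (is.null(shuffle_intervals)) {
      stats::runif(n, 0, duration)
    } else {
      w <- shuffle_intervals$end_s - shuffle_intervals$start_s
      k <- sample.int(nrow(shuffle_intervals), n, replace = TRUE,
                      prob = w / sum(w))
      stats::runif(n, shuffle_intervals$start_s[k], shuffle_intervals$end_s[k])
    }
  }
  shuf <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      vstat(draw(length(event_times)))[1]
    }, numeric(1))
  })
  list(strength = obs[1], preferred_phase = obs[2],
       p_value = mean(shuf >= obs[1], na.rm = TRUE),
       n_events = length(event_times))
}

#' Histogram of event phases around the preferred phase
#'
#' Signed circular difference between each event's phase and the session's
#' preferred phase, wrapped to (-180, 180] degrees and binned.
#'
#' @param event_times event times (s).
#' @param ps a `phase_series`.
#' @param preferred_phase preferred phase in radians.
#' @param bin_deg bin width in degrees.
#' @return tibble with `bin_center_deg`, `n`, plus attribute-free
#'   `deviation_deg` per event in column form via `deviations`.
#' @export
phase_deviation_histogram <- function(event_times, ps, preferred_phase,
                                      bin_deg = 15) {
  dev <- wrap_pi(phase_at(ps, event_times)$phi - preferred_phase) * 180 / pi
  nb <- as.integer(round(360 / bin_deg))
  idx <- pmin(pmax(ceiling((dev + 180) / bin_deg), 1L), nb)  # bins (lo, hi]
  out <- tibble::tibble(
    bin_center_deg = -180 + (seq_len(nb) - 0.5) * bin_deg,
    n = tabulate(idx, nbins = nb)
  )
  attr(out, "deviation_deg") <- dev
  out
}
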
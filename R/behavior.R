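#' Classify behavioral states from speed
#'
#' Per-sample labels (locomotion if speed > 3 cm/s, immobility if < 1 cm/s,
#' unclassified between) merged into maximal half-open intervals. Pure
#' thresholds: no hysteresis or minimum duration, so single-sample states are
#' allowed.
#'
#' @param speed_cm_s nonnegative speed series at the imaging rate.
#' @param sampling_rate_hz sampling rate of `speed_cm_s` in Hz.
#' @param loco_min,immo_max state thresholds in cm/s.
#' @return tibble with columns `state` ("locomotion", "immobility",
#'   "unclassified"), `start_s`, `end_s` (half-open), ordered by start.
#' @export
classify_states <- function(speed_cm_s, sampling_rate_hz = 2000,
                            loco_min = 3, immo_max = 1) {
  stopifnot(all(is.finite(speed_cm_s)), all(speed_cm_s >= 0))
  lab <- ifelse(speed_cm_s > loco_min, "locomotion",
                ifelse(speed_cm_s < immo_max, "immobility", "unclassified"))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    state = r$values,
    start_s = (starts - 1L) / sampling_rate_hz,
    end_s = ends / sampling_rate_hz
  )
}

# Intervals of one state as a two-column tibble (start_s, end_s).
state_intervals <- function(states, which_state) {
  dplyr::filter(states, .data$state == which_state)[, c("start_s", "end_s")]
}

#' State-conditioned mean firing rates
#'
#' Spikes inside each state's intervals divided by the total state duration.
#'
#' @param spike_times spike times in seconds.
#' @param states state tibble from [classify_states()].
#' @return tibble with one row per state: `state`, `n_spikes`, `duration_s`,
#'   `rate_hz` (NA with a flag when the state has zero duration).
#' @export
state_rates <- function(spike_times, states) {
  purrr::map_dfr(c("locomotion", "immobility", "unclassified"), function(s) {
    iv <- state_intervals(states, s)
    dur <- interval_total(iv)
    n <- sum(in_intervals(spike_times, iv))
    tibble::tibble(state = s, n_spikes = n, duration_s = dur,
                   rate_hz = if (dur > 0) n / dur else NA_real_,
                   defined = dur > 0)
  })
}

#' Correlation between instantaneous firing rate and speed
#'
#' The instantaneous rate is the spike train convolved with a unit-area
#' Gaussian kernel whose FWHM is `kernel_ms` (sigma = FWHM / 2.355). Pearson
#' correlation with the speed series across all samples.
#'
#' @param spike_times spike times in seconds.
#' @param speed_cm_s speed series at the imaging rate.
#' @param sampling_rate_hz rate of the speed series.
#' @param kernel_ms Gaussian FWHM in milliseconds.
#' @return list with `r` (Pearson coefficient) and `rate_hz` (the smoothed
#'   instantaneous-rate series).
#' @export
rate_speed_correlation <- function(spike_times, speed_cm_s,
                                   sampling_rate_hz = 2000, kernel_ms = 250) {
  if (length(spike_times) < 2) stop("need at least 2 spikes", call. = FALSE)
  if (stats::sd(speed_cm_s) == 0) {
    stop("undefined correlation: zero-variance speed", call. = FALSE)
  }
  rate <- instantaneous_rate(spike_times, length(speed_cm_s),
                             sampling_rate_hz, kernel_ms)
  list(r = stats::cor(rate, speed_cm_s), rate_hz = rate)
}

# Gaussian-smoothed instantaneous rate (Hz) on the imaging sample grid.
instantaneous_rate <- function(spike_times, n_samples, sampling_rate_hz,
                               kernel_ms = 250) {
  sigma_s <- kernel_ms / 1000 / (2 * sqrt(2 * log(2)))
  sigma_samp <- sigma_s * sampling_rate_hz
  half <- ceiling(4 * sigma_samp)
  kern <- stats::dnorm(seq(-half, half), sd = sigma_samp)
  kern <- kern / sum(kern)
  train <- numeric(n_samples)
  idx <- align_indices(spike_times, sampling_rate_hz) + 1L
  idx <- idx[idx >= 1 & idx <= n_samples]
  for (i in idx) train[i] <- train[i] + sampling_rate_hz  # delta of area 1 s
  full <- stats::convolve(train, rev(kern), type = "open")  # FFT convolution
  full[(half + 1L):(half + n_samples)]
}
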
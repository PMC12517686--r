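#' Occupancy-normalized spatial tuning curve
#'
#' Divides the one-way track into equal bins (36 bins of 2.5 cm on the
#' default 90 cm track), restricts spikes and occupancy to samples with speed
#' above `speed_min`, and computes rate = spike count / dwell time per bin.
#' Bins with zero occupancy are masked (NA) and excluded downstream.
#'
#' @param spike_times spike times (s).
#' @param behavior a `behavior_track` (timestamps, position, speed).
#' @param n_bins number of spatial bins.
#' @param track_cm track length (cm); bins are half-open
#'   `[b * track_cm / n_bins, (b+1) * track_cm / n_bins)`.
#' @param speed_min speed threshold (cm/s) for both spikes and occupancy.
#' @return A `tuning_curve` object: tibble `bins` (`bin`, `bin_center_cm`,
#'   `rate_hz`, `occupancy_s`, `n_spikes`), scalars `peak_rate_hz`,
#'   `selectivity`, `is_place_cell`.
#' @export
tuning_curve <- function(spike_times, behavior, n_bins = 36, track_cm = 90,
                         speed_min = 3) {
  t <- behavior$t
  dt <- diff(t)
  dt <- c(dt, dt[length(dt)])   # sample i covers [t_i, t_i + dt_i)
  moving <- behavior$speed_cm_s > speed_min
  bin_of <- function(pos) pmin(floor(pos / (track_cm / n_bins)), n_bins - 1L) + 1L
  occ <- numeric(n_bins)
  sel <- which(moving)
  if (length(sel) > 0) {
    occ_tab <- tapply(dt[sel], bin_of(behavior$position_cm[sel]), sum)
    occ[as.integer(names(occ_tab))] <- occ_tab
  }
  if (all(occ == 0)) stop("undefined tuning curve: no occupied bins", call. = FALSE)
  counts <- numeric(n_bins)
  if (length(spike_times) > 0) {
    si <- findInterval(spike_times, t)
    ok <- si >= 1 & moving[pmax(si, 1L)]
    sb <- bin_of(behavior$position_cm[si[ok]])
    tb <- tabulate(sb, nbins = n_bins)
    counts <- as.numeric(tb)
  }
  rate <- ifelse(occ > 0, counts / occ, NA_real_)
  bins <- tibble::tibble(
    bin = seq_len(n_bins) - 1L,
    bin_center_cm = (seq_len(n_bins) - 0.5) * track_cm / n_bins,
    rate_hz = rate, occupancy_s = occ, n_spikes = counts
  )
  curve <- structure(
    list(bins = bins, n_bins = n_bins, track_cm = track_cm,
         peak_rate_hz = max(rate, na.rm = TRUE)),
    class = "tuning_curve"
  )
  curve$selectivity <- tryCatch(spatial_selectivity(curve),
                                error = function(e) NA_real_)
  curve$is_place_cell <- classify_place_cell(curve)
  curve
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("<tuning_curve> peak ", signif(x$peak_rate_hz, 3), " Hz, selectivity ",
      signif(x$selectivity, 3), ", place cell: ", x$is_place_cell, "\n",
      sep = "")
  invisible(x)
}

#' Spatial selectivity (one minus circular variance)
#'
#' Maps bin centers to angles on the circle (`theta_b = 2 pi (b + 0.5) /
#' n_bins`) and computes the rate-weighted mean resultant length over defined
#' bins: `|sum_b rate_b exp(i theta_b)| / sum_b rate_b`.
#'
#' @param curve a `tuning_curve`.
#' @return selectivity in `[0, 1]`.
#' @export
spatial_selectivity <- function(curve) {
  ok <- !is.na(curve$bins$rate_hz)
  r <- curve$bins$rate_hz[ok]
  if (sum(r) <= 0) stop("undefined selectivity: all-zero rates", call. = FALSE)
  theta <- 2 * pi * (curve$bins$bin[ok] + 0.5) / curve$n_bins
  Mod(sum(r * exp(1i * theta))) / sum(r)
}

#' Place-cell classification
#'
#' TRUE iff selectivity exceeds 0.25 (strict) and peak rate exceeds 1 Hz.
#'
#' @param curve a `tuning_curve`.
#' @param min_selectivity,min_peak_hz thresholds.
#' @return logical.
#' @export
classify_place_cell <- function(curve, min_selectivity = 0.25,
                                min_peak_hz = 1) {
  sel <- curve$selectivity
  if (is.null(sel) || is.na(sel)) return(FALSE)
  sel > min_selectivity && curve$peak_rate_hz > min_peak_hz
}

#' Spearman similarity of two tuning curves
#'
#' Spearman rank correlation over jointly defined (occupied) bins.
#'
#' @param curve_a,curve_b `tuning_curve` objects.
#' @return Spearman rho.
#' @export
tuning_similarity <- function(curve_a, curve_b) {
  ra <- curve_a$bins$rate_hz
  rb <- curve_b$bins$rate_hz
  ok <- !is.na(ra) & !is.na(rb)
  if (sum(ok) < 3) stop("need at least 3 jointly defined bins", call. = FALSE)
  if (stats::sd(ra[ok]) == 0 || stats::sd(rb[ok]) == 0) {
    stop("undefined correlation: constant curve", call. = FALSE)
  }
  stats::cor(ra[ok], rb[ok], method = "spearman")
}

#' Synchronization strength versus tuning similarity across pairs
#'
#' Spearman correlation between per-pair synchronization strength (from
#' state-restricted pairwise CCGs) and tuning-curve similarity, with a
#' permutation p-value.
#'
#' @param pairs tibble (or data frame) with columns `sync_strength` and
#'   `similarity`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `rho`, `p_value`, `n_pairs`.
#' @export
synchrony_vs_tuning <- function(pairs, n_perm = 10000, seed = 1) {
  x <- pairs$sync_strength
  y <- pairs$similarity
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 pairs with defined values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: degenerate input", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      stats::cor(x, sample(y), method = "spearman")
    }, numeric(1))
  })
  list(rho = rho, p_value = mean(abs(perm) >= abs(rho)),
       n_pairs = length(x))
}
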
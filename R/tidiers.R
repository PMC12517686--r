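#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-correlogram into a tibble of bins
#'
#' @param x a `ccg` object.
#' @param ... unused.
#' @return tibble with `lag_ms` and `count`.
#' @method tidy ccg
#' @export
tidy.ccg <- function(x, ...) {
  tibble::tibble(lag_ms = x$lags_ms, count = x$counts)
}

#' One-row summary of a cross-correlogram
#'
#' @param x a `ccg` object.
#' @param ... unused.
#' @return tibble with peak lag/value, FWHM and (for pairwise CCGs)
#'   synchronization strength and p-value.
#' @method glance ccg
#' @export
glance.ccg <- function(x, ...) {
  tibble::tibble(
    peak_lag_ms = x$peak_lag_ms, peak_value = x$peak_value,
    fwhm_ms = x$fwhm_ms %||% NA_real_,
    sync_strength = x$sync_strength %||% NA_real_,
    p_value = x$p_value %||% NA_real_,
    n_pair_counts = x$n_pair_counts %||% NA_real_
  )
}

#' Tidy detected synchrony events
#'
#' @param x a `sync_events` object.
#' @param ... unused.
#' @return the per-event tibble (one row per event, without the participant
#'   list-column).
#' @method tidy sync_events
#' @export
tidy.sync_events <- function(x, ...) {
  dplyr::select(x$events, -"participants")
}

#' One-row summary of a synchrony detection
#'
#' @param x a `sync_events` object.
#' @param ... unused.
#' @return tibble with event count and rate, median ensemble size, and the
#'   detection parameters.
#' @method glance sync_events
#' @export
glance.sync_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    event_rate_hz = nrow(x$events) / x$duration_s,
    median_ensemble_size_pct = if (nrow(x$events) > 0)
      stats::median(x$events$ensemble_size_pct) else NA_real_,
    n_cells = x$n_cells, window_ms = x$window_ms, k_sd = x$k_sd,
    n_jitters = x$n_jitters
  )
}

#' Tidy a spatial tuning curve
#'
#' @param x a `tuning_curve` object.
#' @param ... unused.
#' @return the per-bin tibble.
#' @method tidy tuning_curve
#' @export
tidy.tuning_curve <- function(x, ...) x$bins

#' One-row summary of a spatial tuning curve
#'
#' @param x a `tuning_curve` object.
#' @param ... unused.
#' @return tibble with peak rate, selectivity and classification.
#' @method glance tuning_curve
#' @export
glance.tuning_curve <- function(x, ...) {
  tibble::tibble(peak_rate_hz = x$peak_rate_hz, selectivity = x$selectivity,
                 is_place_cell = x$is_place_cell)
}
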
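# Internal numerical helpers shared across modules.

#' Moving average with truncated (shrunken) edge windows
#'
#' Mean of `x` over a centered window of `halfwidth` samples on each side;
#' windows are truncated at the trace boundaries, never padded.
#'
#' @param x numeric vector.
#' @param halfwidth integer, samples on each side of the center.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, halfwidth) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered rolling sum over window [i - before, i + after], truncated at edges.
rolling_sum <- function(x, before, after) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  cs[hi + 1L] - cs[lo]
}

#' Analytic signal via the FFT
#'
#' Standard frequency-domain construction: double the positive frequencies,
#' zero the negative ones, keep DC (and Nyquist for even lengths) untouched.
#'
#' @param x real numeric vector.
#' @return complex vector; `Mod()` is the envelope, `Arg()` the phase.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase Butterworth band-pass (forward-backward). Bands far below the
# Nyquist rate make the polynomial filter numerically unstable (normalized
# cutoffs ~1e-3), so the signal is decimated first (after an anti-alias
# low-pass), filtered at the reduced rate, and interpolated back onto the
# original grid — exact for a band-limited result.
bandpass_filtfilt <- function(x, band_hz, fs, order = 4) {
  nyq <- fs / 2
  if (band_hz[1] <= 0 || band_hz[2] >= nyq) {
    stop("band [", band_hz[1], ", ", band_hz[2], "] Hz outside (0, ", nyq, ")",
         call. = FALSE)
  }
  dec <- max(1L, floor(fs / (band_hz[2] * 40)))
  if (dec > 1L) {
    fs2 <- fs / dec
    aa <- signal::butter(4, 0.8 * (fs2 / 2) / nyq, type = "low")
    xd <- signal::filtfilt(aa, x)[seq(1L, length(x), by = dec)]
    bf <- signal::butter(order, band_hz / (fs2 / 2), type = "pass")
    yd <- signal::filtfilt(bf, xd)
    t0 <- (seq_along(xd) - 1L) * dec + 1L
    stats::approx(t0, yd, xout = seq_along(x), rule = 2)$y
  } else {
    bf <- signal::butter(order, band_hz / nyq, type = "pass")
    signal::filtfilt(bf, x)
  }
}

lowpass_filtfilt <- function(x, cutoff_hz, fs, order = 2) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Evaluate the RNG-dependent expression under a temporary seed, restoring the
# caller's RNG state afterwards. All stochastic operations route through this
# so a master seed fully determines every result.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from one master seed; offsets are fixed
# per stage so reruns are reproducible. Kept below 2^31 - 1.
derive_seed <- function(master_seed, offset) {
  (as.numeric(master_seed) * 1000 + offset) %% 2147483647
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Total time covered by a two-column [start, end) interval matrix/data frame.
interval_total <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  sum(intervals[[2]] - intervals[[1]])
}

# TRUE for each time that falls inside any half-open [start, end) interval.
in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(t)))
  }
  starts <- intervals[[1]]
  ends <- intervals[[2]]
  idx <- findInterval(t, starts)
  idx > 0 & t < ends[pmax(idx, 1L)]
}

# Maximal runs of TRUE in a logical vector -> integer matrix [start, end]
# (inclusive sample indices).
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Deterministic full-precision CSV writer: doubles as %.17g so text
# round-trips bit-identically and repeated saves are byte-identical.
write_numeric_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
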
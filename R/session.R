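#' Session containers for simultaneous voltage imaging, LFP, and behavior
#'
#' A session bundle holds everything recorded simultaneously in one imaging
#' session: per-cell fluorescence traces sampled at the imaging rate (2 kHz by
#' default), one LFP channel at an integer multiple of the imaging rate (8 kHz
#' by default), and behavior tracking (linearized position and speed) stored at
#' the imaging rate so the whole bundle shares two timebases. Imaging frame 0
#' defines t = 0; sample `i` covers the half-open interval `[i/fs, (i+1)/fs)`.
#'
#' @param cells list of cell traces from [cell_trace()].
#' @param lfp LFP trace from [lfp_trace()].
#' @param behavior behavior track from [behavior_track()].
#' @param session_id character scalar.
#' @param duration_s session duration in seconds.
#' @param track_length_cm length of the one-way track in cm.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(cells, lfp, behavior, session_id, duration_s,
                           track_length_cm = 90) {
  b <- structure(
    list(cells = cells, lfp = lfp, behavior = behavior,
         session_id = as.character(session_id),
         duration_s = as.numeric(duration_s),
         track_length_cm = as.numeric(track_length_cm)),
    class = "session_bundle"
  )
  validate_session_bundle(b)
}

#' @rdname session_bundle
#' @param cell_id character id of the cell.
#' @param raw_f numeric vector of raw fluorescence (a.u.) per sample.
#' @param centroid_xy numeric length-2 ROI centroid in micrometers.
#' @param sampling_rate_hz imaging rate in Hz.
#' @export
cell_trace <- function(cell_id, raw_f, centroid_xy,
                       sampling_rate_hz = 2000) {
  stopifnot(length(centroid_xy) == 2)
  if (!all(is.finite(raw_f))) stop("raw_f must be finite", call. = FALSE)
  if (!all(is.finite(centroid_xy))) stop("centroid_xy must be finite", call. = FALSE)
  structure(
    list(cell_id = as.character(cell_id), raw_f = as.numeric(raw_f),
         centroid_xy = as.numeric(centroid_xy),
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "cell_trace"
  )
}

#' @rdname session_bundle
#' @param samples numeric LFP samples in microvolts.
#' @export
lfp_trace <- function(samples, sampling_rate_hz = 8000) {
  if (!all(is.finite(samples))) stop("lfp samples must be finite", call. = FALSE)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "lfp_trace"
  )
}

#' @rdname session_bundle
#' @param t numeric timestamps in seconds, strictly increasing.
#' @param position_cm linearized position on the one-way track.
#' @param speed_cm_s nonnegative speed in cm/s.
#' @export
behavior_track <- function(t, position_cm, speed_cm_s) {
  stopifnot(length(t) == length(position_cm), length(t) == length(speed_cm_s))
  if (any(diff(t) <= 0)) stop("behavior timestamps must be strictly increasing", call. = FALSE)
  if (any(speed_cm_s < 0)) stop("speed_cm_s must be nonnegative", call. = FALSE)
  structure(
    list(t = as.numeric(t), position_cm = as.numeric(position_cm),
         speed_cm_s = as.numeric(speed_cm_s)),
    class = "behavior_track"
  )
}

validate_session_bundle <- function(b) {
  rates <- vapply(b$cells, function(cc) cc$sampling_rate_hz, numeric(1))
  lens <- vapply(b$cells, function(cc) length(cc$raw_f), numeric(1))
  if (length(unique(rates)) != 1 || length(unique(lens)) != 1) {
    stop("all cell traces must share one sampling rate and equal length",
         call. = FALSE)
  }
  ratio <- b$lfp$sampling_rate_hz / rates[1]
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("alignment error: lfp rate ", b$lfp$sampling_rate_hz,
         " is not an integer multiple of imaging rate ", rates[1],
         call. = FALSE)
  }
  if (any(b$behavior$t < 0 | b$behavior$t > b$duration_s)) {
    stop("behavior timestamps outside [0, duration_s]", call. = FALSE)
  }
  if (any(b$behavior$position_cm < 0 |
          b$behavior$position_cm > b$track_length_cm)) {
    stop("position_cm outside [0, track_length]", call. = FALSE)
  }
  b$lfp_imaging_ratio <- as.integer(round(ratio))
  b
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> ", x$session_id, "\n",
      "  cells: ", length(x$cells), " @ ",
      x$cells[[1]]$sampling_rate_hz, " Hz, ",
      length(x$cells[[1]]$raw_f), " samples\n",
      "  lfp:   ", length(x$lfp$samples), " samples @ ",
      x$lfp$sampling_rate_hz, " Hz (ratio ", x$lfp_imaging_ratio, ")\n",
      "  duration: ", x$duration_s, " s, track ", x$track_length_cm, " cm\n",
      sep = "")
  invisible(x)
}

#' Imaging rate of a session bundle (Hz)
#' @param bundle a `session_bundle`.
#' @return numeric scalar.
#' @export
imaging_rate <- function(bundle) bundle$cells[[1]]$sampling_rate_hz

#' Save a session bundle to a directory of plain-text files
#'
#' The on-disk layout is a directory with `session.json` (root attributes and
#' per-cell centroids), `cells.csv` (one column per cell of raw fluorescence),
#' `lfp.csv` and `behavior.csv`. Numeric payloads are written at full
#' precision (`%.17g`) so a save/load round trip is bit-identical and two
#' saves of the same bundle are byte-identical.
#'
#' @param bundle a `session_bundle`.
#' @param path directory to create.
#' @param overwrite logical; an existing path is refused unless `TRUE`.
#' @return `path`, invisibly.
#' @export
save_session <- function(bundle, path, overwrite = FALSE) {
  if (dir.exists(path) || file.exists(path)) {
    if (!overwrite) stop("path exists (use overwrite = TRUE): ", path, call. = FALSE)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  meta <- list(
    session_id = bundle$session_id,
    duration_s = bundle$duration_s,
    imaging_rate_hz = imaging_rate(bundle),
    lfp_rate_hz = bundle$lfp$sampling_rate_hz,
    track_length_cm = bundle$track_length_cm,
    cell_ids = vapply(bundle$cells, function(cc) cc$cell_id, character(1)),
    centroids_um = lapply(bundle$cells, function(cc) cc$centroid_xy)
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cells_df <- as.data.frame(lapply(bundle$cells, function(cc) cc$raw_f))
  names(cells_df) <- meta$cell_ids
  write_numeric_csv(cells_df, file.path(path, "cells.csv"))
  write_numeric_csv(data.frame(samples = bundle$lfp$samples),
                    file.path(path, "lfp.csv"))
  write_numeric_csv(
    data.frame(t = bundle$behavior$t,
               position_cm = bundle$behavior$position_cm,
               speed_cm_s = bundle$behavior$speed_cm_s),
    file.path(path, "behavior.csv"))
  invisible(path)
}

#' Load a session bundle saved by [save_session()]
#'
#' @param path directory written by [save_session()].
#' @return A validated `session_bundle`.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop("no session bundle at: ", path, call. = FALSE)
  need <- c(session = "session.json", cells = "cells.csv", lfp = "lfp.csv",
            behavior = "behavior.csv")
  for (key in names(need)) {
    if (!file.exists(file.path(path, need[[key]]))) {
      stop("format error: bundle is missing \"", key, "\" (", need[[key]], ")",
           call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  cells_df <- data.table::fread(file.path(path, "cells.csv"),
                                colClasses = "numeric", data.table = FALSE)
  centroids <- meta$centroids_um
  if (is.matrix(centroids)) centroids <- asplit(centroids, 1)
  cells <- lapply(seq_along(meta$cell_ids), function(i) {
    cell_trace(meta$cell_ids[i], cells_df[[i]], as.numeric(centroids[[i]]),
               meta$imaging_rate_hz)
  })
  lfp_df <- data.table::fread(file.path(path, "lfp.csv"),
                              colClasses = "numeric", data.table = FALSE)
  beh_df <- data.table::fread(file.path(path, "behavior.csv"),
                              colClasses = "numeric", data.table = FALSE)
  session_bundle(
    cells = cells,
    lfp = lfp_trace(lfp_df$samples, meta$lfp_rate_hz),
    behavior = behavior_track(beh_df$t, beh_df$position_cm, beh_df$speed_cm_s),
    session_id = meta$session_id,
    duration_s = meta$duration_s,
    track_length_cm = meta$track_length_cm
  )
}

#' Map an event time to the nearest sample index at a target rate
#'
#' Half-up tie-break: an event exactly halfway between two samples maps to the
#' later one. Index 0 is the first sample.
#'
#' @param t_event event time(s) in seconds.
#' @param target_rate_hz sampling rate of the target series.
#' @param duration_s recording duration; events outside `[0, duration_s]` error.
#' @return integer sample indices (0-based).
#' @export
align_indices <- function(t_event, target_rate_hz, duration_s = Inf) {
  if (any(t_event < 0 | t_event > duration_s)) {
    stop("t_event outside recording [0, ", duration_s, "]", call. = FALSE)
  }
  as.integer(floor(t_event * target_rate_hz + 0.5))
}
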
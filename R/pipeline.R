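# Greedy one-to-one matching of detected to reference event times within a
# tolerance; returns indices and hit counts for precision/recall scoring.
match_events <- function(detected, reference, tol_s) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (r in reference) {
    d <- abs(detected - r)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(hits = hits,
       recall = if (length(reference) > 0) hits / length(reference) else NA_real_,
       precision = if (length(detected) > 0) hits / length(detected) else NA_real_)
}

#' Run the full analysis pipeline on a session bundle
#'
#' Executes preprocessing, behavioral-state segmentation, population-synchrony
#' detection, correlograms, LFP oscillation analysis, subVm dynamics, and
#' spatial tuning, in that order. All stochastic stages derive their seeds
#' from the single `master_seed`. When `out_dir` is given, CSV exports, a
#' JSON summary and a run log are written; the JSON summary is a pure
#' function of (bundle, options, master_seed), so reruns are byte-identical.
#'
#' @param bundle a `session_bundle`.
#' @param master_seed integer master seed.
#' @param out_dir optional output directory.
#' @param n_jitters_sync surrogates for synchrony detection.
#' @param n_jitters_ccg jitter iterations per cell pair.
#' @param n_shuffles shuffles for modulation statistics.
#' @param max_pairs cap on the number of cell pairs analyzed (NULL = all).
#' @param stages character vector of stage names to run (dependencies of a
#'   requested stage are always run); subVm and spatial stages depend only on
#'   imaging, so disabling "lfp" does not disable them.
#' @return A `voltsync_run` list of per-stage results plus `summary`.
#' @export
run_pipeline <- function(bundle, master_seed, out_dir = NULL,
                         n_jitters_sync = 500, n_jitters_ccg = 200,
                         n_shuffles = 500, max_pairs = NULL,
                         stages = c("synchrony", "correlograms", "lfp",
                                    "subvm", "spatial")) {
  fs <- imaging_rate(bundle)
  dur <- bundle$duration_s
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  pre <- run_stage("preprocess", preprocess_session(bundle))
  trains <- lapply(pre$activities[pre$qc$included], `[[`, "spike_times")
  subvms <- lapply(pre$activities[pre$qc$included], `[[`, "subvm")
  centroids <- do.call(rbind, lapply(bundle$cells, function(cc) cc$centroid_xy))
  rownames(centroids) <- vapply(bundle$cells, function(cc) cc$cell_id,
                                character(1))
  centroids_inc <- centroids[pre$qc$included, , drop = FALSE]

  states <- run_stage("behavior",
                      classify_states(bundle$behavior$speed_cm_s, fs))
  loco_iv <- state_intervals(states, "locomotion")
  immo_iv <- state_intervals(states, "immobility")
  cell_rates <- purrr::imap_dfr(trains, function(st, id) {
    sr <- state_rates(st, states)
    tibble::tibble(cell_id = id,
                   rate_hz = length(st) / dur,
                   rate_loco_hz = sr$rate_hz[sr$state == "locomotion"],
                   rate_immo_hz = sr$rate_hz[sr$state == "immobility"])
  })

  res <- list(preprocess = pre, states = states, cell_rates = cell_rates,
              master_seed = master_seed)

  if ("synchrony" %in% stages) {
    sync <- run_stage("synchrony", detect_synchrony(
      trains, dur, fs, n_jitters = n_jitters_sync,
      seed = derive_seed(master_seed, 11)))
    res$sync <- sync
    res$sync_rates <- event_rate_segments(sync, dur, 2)
  }

  if ("correlograms" %in% stages) {
    res$grand_ccgs <- run_stage("correlograms", purrr::imap_dfr(
      trains, function(st, id) {
        others <- trains[setdiff(names(trains), id)]
        g <- tryCatch(grand_average_ccg(st, others),
                      error = function(e) NULL)
        if (is.null(g)) return(NULL)
        tibble::tibble(cell_id = id, peak_lag_ms = g$peak_lag_ms,
                       peak_value = g$peak_value, fwhm_ms = g$fwhm_ms)
      }))
    pair_idx <- utils::combn(names(trains), 2, simplify = FALSE)
    if (!is.null(max_pairs) && length(pair_idx) > max_pairs) {
      pair_idx <- pair_idx[seq_len(max_pairs)]
    }
    res$pair_ccgs <- purrr::map_dfr(seq_along(pair_idx), function(k) {
      ab <- pair_idx[[k]]
      pc <- pairwise_ccg(trains[[ab[1]]], trains[[ab[2]]],
                         state_intervals = loco_iv,
                         n_jitters = n_jitters_ccg,
                         seed = derive_seed(master_seed, 100 + k))
      d <- sqrt(sum((centroids_inc[ab[1], ] - centroids_inc[ab[2], ])^2))
      if (inherits(pc, "ccg_excluded")) {
        tibble::tibble(cell_a = ab[1], cell_b = ab[2], state = "locomotion",
                       peak_lag_ms = NA_real_, fwhm_ms = NA_real_,
                       sync_strength = NA_real_, p_value = NA_real_,
                       n_counts = pc$n_pair_counts, soma_dist_um = d,
                       excluded_reason = pc$excluded_reason)
      } else {
        tibble::tibble(cell_a = ab[1], cell_b = ab[2], state = "locomotion",
                       peak_lag_ms = pc$peak_lag_ms, fwhm_ms = pc$fwhm_ms,
                       sync_strength = pc$sync_strength, p_value = pc$p_value,
                       n_counts = pc$n_pair_counts, soma_dist_um = d,
                       excluded_reason = NA_character_)
      }
    })
  }

  if ("lfp" %in% stages) {
    res$ripples <- run_stage("lfp", detect_ripples(bundle$lfp))
    lfp_theta <- phase_series(bundle$lfp$samples, c(4, 12),
                              bundle$lfp$sampling_rate_hz)
    res$lfp_theta <- lfp_theta
    if (!is.null(res$sync) && nrow(res$sync$events) > 0) {
      ev_t <- res$sync$events$event_time_s
      res$sync_theta_mod <- event_phase_modulation(
        ev_t, lfp_theta, n_shuffles = n_shuffles,
        seed = derive_seed(master_seed, 21))
      res$sync_ripple_cooc <- co_occurrence(
        ev_t, res$ripples[, c("start_s", "end_s")])
    }
    if (nrow(res$ripples) > 0) {
      res$ripple_mod <- purrr::imap_dfr(trains, function(st, id) {
        if (length(st) == 0) return(NULL)
        m <- ripple_modulation_index(st, res$ripples, dur,
                                     n_shuffles = n_shuffles,
                                     seed = derive_seed(master_seed, 31))
        tibble::tibble(cell_id = id, index = m$index, p_value = m$p_value)
      })
    }
  }

  if ("subvm" %in% stages) {
    segs <- run_stage("subvm", label_segments(bundle$behavior$speed_cm_s, fs))
    res$segments <- segs
    ids <- names(subvms)
    pair_idx <- utils::combn(ids, 2, simplify = FALSE)
    if (!is.null(max_pairs) && length(pair_idx) > max_pairs) {
      pair_idx <- pair_idx[seq_len(max_pairs)]
    }
    res$subvm_pairs <- purrr::map_dfr(pair_idx, function(ab) {
      coh <- pairwise_theta_coherence(subvms[[ab[1]]], subvms[[ab[2]]],
                                      segs, fs)
      if (nrow(coh) == 0) return(NULL)
      d <- sqrt(sum((centroids_inc[ab[1], ] - centroids_inc[ab[2], ])^2))
      dplyr::mutate(coh, cell_a = ab[1], cell_b = ab[2], soma_dist_um = d)
    })
    if (!is.null(res$subvm_pairs) && nrow(res$subvm_pairs) >= 3) {
      res$coh_dist <- purrr::map(c("immobility", "locomotion"), function(s) {
        dd <- dplyr::filter(res$subvm_pairs, .data$state == s)
        if (nrow(dd) < 3) return(NULL)
        c(coherence_vs_distance(dd$theta_coherence, dd$soma_dist_um),
          list(state = s))
      })
    }
    if (!is.null(res$sync) && nrow(res$sync$events) > 0) {
      res$sync_subvm <- synchrony_triggered_subvm(
        subvms, trains, res$sync$events$event_time_s, fs)
    }
  }

  if ("spatial" %in% stages) {
    res$tuning <- run_stage("spatial", purrr::imap(trains, function(st, id) {
      tryCatch(tuning_curve(st, bundle$behavior,
                            track_cm = bundle$track_length_cm),
               error = function(e) NULL)
    }))
    res$tuning <- purrr::compact(res$tuning)
    res$place_table <- purrr::imap_dfr(res$tuning, function(tc, id) {
      tibble::tibble(cell_id = id, peak_rate_hz = tc$peak_rate_hz,
                     selectivity = tc$selectivity,
                     is_place_cell = tc$is_place_cell)
    })
    if (!is.null(res$pair_ccgs)) {
      pc_ids <- res$place_table$cell_id[res$place_table$is_place_cell]
      pairs <- dplyr::filter(res$pair_ccgs,
                             .data$cell_a %in% pc_ids &
                               .data$cell_b %in% pc_ids &
                               is.na(.data$excluded_reason))
      if (nrow(pairs) >= 5) {
        sim <- vapply(seq_len(nrow(pairs)), function(k) {
          tryCatch(tuning_similarity(res$tuning[[pairs$cell_a[k]]],
                                     res$tuning[[pairs$cell_b[k]]]),
                   error = function(e) NA_real_)
        }, numeric(1))
        st_df <- tibble::tibble(sync_strength = pairs$sync_strength,
                                similarity = sim)
        res$sync_vs_tuning <- tryCatch(
          synchrony_vs_tuning(st_df, n_perm = 2000,
                              seed = derive_seed(master_seed, 41)),
          error = function(e) NULL)
        res$sync_tuning_pairs <- st_df
      }
    }
  }

  res$summary <- pipeline_summary(res)
  class(res) <- "voltsync_run"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Deterministic JSON-ready summary of the headline quantities.
pipeline_summary <- function(res) {
  s <- list(
    master_seed = res$master_seed,
    n_cells_analyzable = length(res$preprocess$qc$included),
    session_analyzable = res$preprocess$qc$analyzable,
    median_rate_hz = stats::median(res$cell_rates$rate_hz)
  )
  if (!is.null(res$sync)) {
    s$n_sync_events <- nrow(res$sync$events)
    s$sync_rate_hz <- nrow(res$sync$events) / res$sync$duration_s
    if (nrow(res$sync$events) > 0) {
      s$median_ensemble_size_pct <-
        stats::median(res$sync$events$ensemble_size_pct)
    }
  }
  if (!is.null(res$grand_ccgs) && nrow(res$grand_ccgs) > 0) {
    s$grand_ccg_fwhm_ms_mean <- mean(res$grand_ccgs$fwhm_ms, na.rm = TRUE)
  }
  if (!is.null(res$pair_ccgs)) {
    ok <- is.na(res$pair_ccgs$excluded_reason)
    s$n_pairs_included <- sum(ok)
    if (any(ok)) {
      s$pct_pairs_significant <-
        100 * mean(res$pair_ccgs$p_value[ok] < 0.05)
    }
  }
  if (!is.null(res$ripples)) s$n_ripples <- nrow(res$ripples)
  if (!is.null(res$sync_theta_mod)) {
    s$sync_theta_strength <- res$sync_theta_mod$strength
    s$sync_theta_pref_deg <- res$sync_theta_mod$preferred_phase * 180 / pi
  }
  if (!is.null(res$sync_ripple_cooc)) {
    s$pct_sync_in_ripples <- res$sync_ripple_cooc$pct_events_in_intervals
  }
  if (!is.null(res$subvm_pairs) && nrow(res$subvm_pairs) > 0) {
    med <- stats::aggregate(theta_coherence ~ state, data = res$subvm_pairs,
                            FUN = stats::median)
    for (k in seq_len(nrow(med))) {
      s[[paste0("median_theta_coherence_", med$state[k])]] <-
        med$theta_coherence[k]
    }
  }
  if (!is.null(res$place_table) && nrow(res$place_table) > 0) {
    s$pct_place_cells <- 100 * mean(res$place_table$is_place_cell)
  }
  if (!is.null(res$sync_vs_tuning)) {
    s$sync_vs_tuning_rho <- res$sync_vs_tuning$rho
    s$sync_vs_tuning_p <- res$sync_vs_tuning$p_value
  }
  s
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$preprocess$qc$report,
                   file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  utils::write.csv(res$preprocess$spikes,
                   file.path(out_dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(res$states, file.path(out_dir, "states.csv"),
                   row.names = FALSE)
  if (!is.null(res$sync) && nrow(res$sync$events) > 0) {
    ev <- dplyr::select(res$sync$events, -"participants")
    utils::write.csv(ev, file.path(out_dir, "sync_events.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$pair_ccgs)) {
    utils::write.csv(res$pair_ccgs, file.path(out_dir, "pair_ccgs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$ripples)) {
    utils::write.csv(res$ripples, file.path(out_dir, "ripples.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$subvm_pairs)) {
    utils::write.csv(res$subvm_pairs, file.path(out_dir, "subvm_pairs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$place_table)) {
    utils::write.csv(res$place_table, file.path(out_dir, "place_cells.csv"),
                     row.names = FALSE)
  }
  log_lines <- c(
    paste0("voltsync ", as.character(utils::packageVersion("voltsync"))),
    paste0("master_seed: ", res$master_seed),
    paste0("n_cells: ", nrow(res$preprocess$qc$report))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.voltsync_run <- function(x, ...) {
  cat("<voltsync_run> seed ", x$master_seed, "\n", sep = "")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Score a pipeline run against the generator's ground truth
#'
#' Computes precision/recall for spikes (+/-1 ms), synchrony events
#' (+/-12.5 ms) and ripples (+/-10 ms boundary tolerance), place-field
#' center errors, and the theta preferred-phase recovery error.
#'
#' @param run a `voltsync_run` from [run_pipeline()].
#' @param truth ground-truth ledger from [generate_session()].
#' @return tibble with `metric`, `value`.
#' @export
compare_to_truth <- function(run, truth) {
  out <- list()
  act <- run$preprocess$activities
  ids <- intersect(names(act), names(truth$true_spikes))
  sens <- numeric(0); prec <- numeric(0)
  for (id in ids) {
    m <- match_events(act[[id]]$spike_times, truth$true_spikes[[id]], 0.001)
    sens <- c(sens, m$recall)
    prec <- c(prec, m$precision)
  }
  out$spike_sensitivity <- mean(sens, na.rm = TRUE)
  out$spike_precision <- mean(prec, na.rm = TRUE)
  if (!is.null(run$sync)) {
    m <- match_events(run$sync$events$event_time_s,
                      truth$true_sync_events$event_time_s, 0.0125)
    out$sync_hit_rate <- m$recall
    out$sync_precision <- m$precision
  }
  if (!is.null(run$ripples) && nrow(truth$true_ripples) > 0) {
    m <- match_events((run$ripples$start_s + run$ripples$end_s) / 2,
                      truth$true_ripples$center_s, 0.05)
    out$ripple_recall <- m$recall
    out$ripple_precision <- m$precision
  }
  if (!is.null(run$tuning)) {
    pc <- truth$true_fields[!is.na(truth$true_fields$center_cm), ]
    errs <- numeric(0)
    for (k in seq_len(nrow(pc))) {
      tc <- run$tuning[[pc$cell_id[k]]]
      if (is.null(tc)) next
      est <- tc$bins$bin_center_cm[which.max(tc$bins$rate_hz)]
      d <- abs(est - pc$center_cm[k])
      errs <- c(errs, min(d, tc$track_cm - d))
    }
    if (length(errs) > 0) out$field_center_mae_cm <- mean(errs)
  }
  tibble::tibble(metric = names(out), value = unlist(out))
}
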
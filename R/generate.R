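#' Configuration for the synthetic session generator
#'
#' Defaults encode the study conditions the pipeline assumes: 14 cells imaged
#' at 2 kHz for 180 s on a 90 cm one-way track, state-dependent theta (7 Hz in
#' immobility, 8 Hz in locomotion), ~1 Hz transient synchronous ensembles of
#' ~25 ms recruiting ~40% of cells at a preferred theta phase, immobility-
#' restricted ripples at 0.04 Hz with spiking suppressed inside them, Gaussian
#' place fields for 40% of cells, coherent subthreshold theta with
#' distance-dependent attenuation, and a negative-going sensor with bleaching
#' and shot noise.
#'
#' @param n_cells number of imaged cells.
#' @param duration_s session duration (s).
#' @param imaging_rate_hz,lfp_rate_hz sampling rates (Hz).
#' @param track_cm track length (cm).
#' @param theta_hz_loco,theta_hz_immo theta frequency by state (Hz).
#' @param sync_rate_hz mean rate of synchronous ensembles (Hz).
#' @param sync_window_ms ensemble window width (ms).
#' @param participation_p per-cell participation probability per event.
#' @param sync_theta_kappa von Mises concentration of event theta phases.
#' @param sync_pref_phase preferred event phase (rad; 0 = theta peak).
#' @param place_cell_fraction fraction of cells given place fields.
#' @param field_sigma_cm Gaussian field width (cm).
#' @param ripple_rate_immo_hz ripple rate during immobility (Hz).
#' @param ripple_amp_sd ripple burst amplitude in multiples of the
#'   background ripple-band envelope SD.
#' @param ripple_suppression silence all spiking inside ripples.
#' @param field_sync_anticorr couple sync participation to maximally spaced
#'   place fields (for tuning-vs-synchrony tests).
#' @param base_rate_median_hz median of the lognormal baseline firing rates.
#' @param immo_rate_mult firing-rate multiplier during immobility.
#' @param background_kappa von Mises concentration of background-spike
#'   theta locking.
#' @param subvm_theta_amp theta amplitude of the subVm proxy (dF/F units).
#' @param subvm_noise_sd slow independent subVm noise SD (dF/F units).
#' @param sync_bump_amp subVm depolarization bump at sync events (dF/F).
#' @param noise_sd white imaging-noise SD as a fraction of baseline F.
#' @param bleach_tau_s bleaching time constant (s).
#' @param spike_amp spike transient amplitude (dF/F units).
#' @param spike_fwhm_ms spike transient FWHM (ms).
#' @param loco_speed_mean,loco_speed_sd locomotion speed distribution (cm/s).
#' @param seed RNG seed (mandatory; all generator randomness flows from it).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cells = 14, duration_s = 180,
                             imaging_rate_hz = 2000, lfp_rate_hz = 8000,
                             track_cm = 90,
                             theta_hz_loco = 8, theta_hz_immo = 7,
                             sync_rate_hz = 1.0, sync_window_ms = 25,
                             participation_p = 0.4, sync_theta_kappa = 4,
                             sync_pref_phase = -pi / 4,
                             place_cell_fraction = 0.4, field_sigma_cm = 5,
                             ripple_rate_immo_hz = 0.04, ripple_amp_sd = 8,
                             ripple_suppression = TRUE,
                             field_sync_anticorr = FALSE,
                             base_rate_median_hz = 3, immo_rate_mult = 1.5,
                             background_kappa = 0.5,
                             subvm_theta_amp = 0.008, subvm_noise_sd = 0.003,
                             sync_bump_amp = 0.004,
                             noise_sd = 0.004, bleach_tau_s = 300,
                             spike_amp = 0.06, spike_fwhm_ms = 1,
                             loco_speed_mean = 8.3, loco_speed_sd = 2,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(participation_p >= 0, participation_p <= 1,
            place_cell_fraction >= 0, place_cell_fraction <= 1,
            sync_rate_hz >= 0, ripple_rate_immo_hz >= 0)
  if (participation_p * n_cells < 2) {
    stop("infeasible config: expected ensemble smaller than 2 cells", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

# von Mises sampler (Best & Fisher 1979 rejection scheme).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_pi(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Generate a behavior track with alternating locomotion/immobility bouts
#'
#' Bout durations are exponential (locomotion mean 8 s, immobility mean
#' 5.5 s) with 1 s linear speed ramps between states, targeting time
#' fractions of roughly 55/35/10% (locomotion/immobility/transition).
#' Locomotion speed is drawn per bout from a truncated normal around
#' `loco_speed_mean` and the position advances along the 90 cm one-way loop.
#'
#' @param config a `generator_config`.
#' @param seed RNG seed (defaults to a child of `config$seed`).
#' @return list with `behavior` (a `behavior_track` at the imaging rate) and
#'   `state_schedule` (tibble `state`, `start_s`, `end_s`).
#' @export
generate_behavior <- function(config, seed = derive_seed(config$seed, 1)) {
  fs <- config$imaging_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  with_seed(seed, {
    # bout schedule
    sched <- list()
    t <- 0
    state <- "locomotion"
    while (t < config$duration_s) {
      dur <- if (state == "locomotion") stats::rexp(1, 1 / 8) + 2
             else stats::rexp(1, 1 / 5.5) + 1.5
      dur <- min(dur, config$duration_s - t)
      sched[[length(sched) + 1L]] <- tibble::tibble(
        state = state, start_s = t, end_s = t + dur)
      t <- t + dur
      if (t < config$duration_s) {
        ramp <- min(1, config$duration_s - t)
        sched[[length(sched) + 1L]] <- tibble::tibble(
          state = "transition", start_s = t, end_s = t + ramp)
        t <- t + ramp
      }
      state <- if (state == "locomotion") "immobility" else "locomotion"
    }
    sched <- dplyr::bind_rows(sched)

    speed <- numeric(n)
    tgrid <- (seq_len(n) - 1L) / fs
    prev_speed <- 0
    for (k in seq_len(nrow(sched))) {
      idx <- which(tgrid >= sched$start_s[k] & tgrid < sched$end_s[k])
      if (length(idx) == 0) next
      if (sched$state[k] == "locomotion") {
        v <- max(3.5, stats::rnorm(1, config$loco_speed_mean,
                                   config$loco_speed_sd))
        jit <- stats::rnorm(length(idx), 0, 0.6)
        jit <- moving_average(jit, as.integer(fs / 4)) * sqrt(fs / 4)
        speed[idx] <- pmax(3.2, v + jit)
        prev_speed <- speed[idx[length(idx)]]
      } else if (sched$state[k] == "immobility") {
        speed[idx] <- stats::runif(1, 0.05, 0.5) +
          abs(stats::rnorm(length(idx), 0, 0.08))
        speed[idx] <- pmin(speed[idx], 0.95)
        prev_speed <- speed[idx[length(idx)]]
      } else {
        nxt <- if (k < nrow(sched) && sched$state[k + 1] == "locomotion") {
          config$loco_speed_mean
        } else {
          0.3
        }
        speed[idx] <- prev_speed +
          (nxt - prev_speed) * seq_along(idx) / (length(idx) + 1L)
        prev_speed <- speed[idx[length(idx)]]
      }
    }
    speed <- pmax(speed, 0)
    pos <- (cumsum(speed) / fs) %% config$track_cm
    behavior <- behavior_track(t = tgrid, position_cm = pos,
                               speed_cm_s = speed)
    list(behavior = behavior,
         state_schedule = sched)
  })
}

# Pink (1/f) noise of length n via FFT shaping, unit SD.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  co <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  co <- co / sqrt(f)
  x <- Re(stats::fft(co, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate the LFP channel with state-dependent theta and ripples
#'
#' Theta is an amplitude-modulated sinusoid whose instantaneous frequency is
#' 8 Hz in locomotion and 7 Hz in immobility (smoothed transitions) over pink
#' background noise. Ripple bursts (150-200 Hz, 60-110 ms, Hann envelope) are
#' injected only during immobility at the configured rate, with amplitude a
#' fixed multiple of the background ripple-band envelope SD.
#'
#' @param config a `generator_config`.
#' @param state_schedule schedule tibble from [generate_behavior()].
#' @param seed RNG seed.
#' @return list with `lfp` (an `lfp_trace`), `true_theta_phase` (radians per
#'   LFP sample; 0 = theta peak), `true_ripples` (tibble `start_s`, `end_s`,
#'   `center_s`).
#' @export
generate_lfp <- function(config, state_schedule,
                         seed = derive_seed(config$seed, 2)) {
  fs <- config$lfp_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  tgrid <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    freq <- rep((config$theta_hz_loco + config$theta_hz_immo) / 2, n)
    for (k in seq_len(nrow(state_schedule))) {
      idx0 <- as.integer(round(state_schedule$start_s[k] * fs)) + 1L
      idx1 <- min(as.integer(round(state_schedule$end_s[k] * fs)), n)
      if (idx1 < idx0) next
      freq[idx0:idx1] <- switch(state_schedule$state[k],
        locomotion = config$theta_hz_loco,
        immobility = config$theta_hz_immo,
        (config$theta_hz_loco + config$theta_hz_immo) / 2)
    }
    freq <- moving_average(freq, as.integer(fs / 4))  # smooth 0.5 s transitions
    phase_unwrapped <- cumsum(2 * pi * freq / fs)
    theta_phase <- wrap_pi(phase_unwrapped)
    amp <- 180 + 60 * pink_noise(n)
    amp <- pmax(moving_average(amp, as.integer(fs / 2)), 40)
    theta <- amp * cos(phase_unwrapped)
    noise <- 90 * pink_noise(n)
    lfp <- theta + noise

    # background ripple-band SD for burst-amplitude calibration
    bg_band <- bandpass_filtfilt(lfp, c(120, 240), fs, order = 4)
    bg_sd <- stats::sd(bg_band)

    immo <- dplyr::filter(state_schedule, .data$state == "immobility")
    ripples <- list()
    if (nrow(immo) > 0 && config$ripple_rate_immo_hz > 0) {
      for (k in seq_len(nrow(immo))) {
        dur <- immo$end_s[k] - immo$start_s[k]
        n_rip <- stats::rpois(1, config$ripple_rate_immo_hz * dur)
        if (n_rip == 0) next
        centers <- sort(stats::runif(n_rip, immo$start_s[k] + 0.1,
                                     immo$end_s[k] - 0.1))
        for (cc in centers) {
          rip_dur <- stats::runif(1, 0.06, 0.11)
          rip_f <- stats::runif(1, 150, 200)
          i0 <- as.integer(round((cc - rip_dur / 2) * fs)) + 1L
          i1 <- as.integer(round((cc + rip_dur / 2) * fs))
          if (i0 < 1 || i1 > n) next
          m <- i1 - i0 + 1L
          env <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
          burst <- config$ripple_amp_sd * bg_sd * env *
            sin(2 * pi * rip_f * seq(0, m - 1) / fs)
          lfp[i0:i1] <- lfp[i0:i1] + burst
          # core = half-amplitude extent of the Hann envelope (middle half)
          ripples[[length(ripples) + 1L]] <- tibble::tibble(
            start_s = (i0 - 1L) / fs, end_s = i1 / fs, center_s = cc,
            core_start_s = cc - rip_dur / 4, core_end_s = cc + rip_dur / 4)
        }
      }
    }
    true_ripples <- if (length(ripples) > 0) dplyr::bind_rows(ripples) else
      tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                     center_s = numeric(0), core_start_s = numeric(0),
                     core_end_s = numeric(0))
    list(lfp = lfp_trace(lfp, fs), true_theta_phase = theta_phase,
         true_ripples = true_ripples)
  })
}

#' Generate ground-truth spike trains with synchronous ensembles
#'
#' Per-cell baseline intensities are lognormal across cells (median
#' `base_rate_median_hz`), raised during immobility, modulated by Gaussian
#' place fields during locomotion for the place-cell fraction, and locked to
#' the theta phase (von Mises thinning). Synchronous ensembles arrive as a
#' Poisson process; each event is placed at a theta phase drawn von Mises
#' around the preferred phase, recruits each cell with probability
#' `participation_p` (or by alternating anti-correlated assemblies when
#' `field_sync_anticorr`), and participants emit one spike within half the
#' sync window of the event time. Spiking is silenced inside true ripples
#' when `ripple_suppression`; a 2 ms refractory period is enforced with sync
#' spikes taking priority.
#'
#' @param config a `generator_config`.
#' @param behavior behavior list from [generate_behavior()].
#' @param lfp_truth list from [generate_lfp()].
#' @param seed RNG seed.
#' @return list with `true_spikes` (named list per cell), `true_sync_events`
#'   (tibble `event_time_s`, list-column `participants`), `true_fields`
#'   (tibble `cell_id`, `center_cm` or NA), `assemblies` (integer per cell or
#'   NULL).
#' @export
generate_spikes <- function(config, behavior, lfp_truth,
                            seed = derive_seed(config$seed, 3)) {
  fs <- config$imaging_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  ratio <- as.integer(round(config$lfp_rate_hz / fs))
  phase_img <- lfp_truth$true_theta_phase[seq(1L, length.out = n, by = ratio)]
  ids <- sprintf("cell%02d", seq_len(config$n_cells))
  speed <- behavior$behavior$speed_cm_s
  pos <- behavior$behavior$position_cm
  ripples <- lfp_truth$true_ripples
  in_ripple <- in_intervals((seq_len(n) - 1L) / fs,
                            ripples[, c("start_s", "end_s")])
  with_seed(seed, {
    base <- stats::rlnorm(config$n_cells,
                          meanlog = log(config$base_rate_median_hz),
                          sdlog = 0.4)
    n_pc <- round(config$place_cell_fraction * config$n_cells)
    pc_idx <- sort(sample.int(config$n_cells, n_pc))
    centers <- rep(NA_real_, config$n_cells)
    assemblies <- NULL
    if (n_pc > 0) {
      spaced <- (seq_len(n_pc) - 0.5) * config$track_cm / n_pc
      if (config$field_sync_anticorr) {
        # co-participating (same-assembly) cells get maximally spaced fields;
        # cells of opposite assemblies get nearly overlapping fields
        # (offset ~0.8 sigma), so field overlap anti-correlates with shared
        # sync participation
        n1 <- ceiling(n_pc / 2)
        a1_centers <- (seq_len(n1) - 0.5) * config$track_cm / n1
        a2_centers <- (a1_centers + 0.8 * config$field_sigma_cm) %%
          config$track_cm
        assemblies <- integer(config$n_cells)
        assemblies[pc_idx] <- rep(c(1L, 2L), length.out = n_pc)
        assemblies[-pc_idx] <- rep(c(1L, 2L),
                                   length.out = config$n_cells - n_pc)
        centers[pc_idx[assemblies[pc_idx] == 1L]] <-
          a1_centers[seq_len(sum(assemblies[pc_idx] == 1L))]
        centers[pc_idx[assemblies[pc_idx] == 2L]] <-
          a2_centers[seq_len(sum(assemblies[pc_idx] == 2L))]
      } else {
        centers[pc_idx] <- sample(spaced)
      }
    }
    if (is.null(assemblies) && config$field_sync_anticorr) {
      assemblies <- rep(c(1L, 2L), length.out = config$n_cells)
    }

    loco_mask <- speed > 3
    state_mult <- ifelse(speed < 1, config$immo_rate_mult, 1)
    phase_mod <- exp(config$background_kappa *
                       cos(phase_img - config$sync_pref_phase)) /
      besselI(config$background_kappa, 0)

    # synchronous events: Poisson times snapped to a von Mises theta phase
    n_ev <- stats::rpois(1, config$sync_rate_hz * config$duration_s)
    ev_t0 <- sort(stats::runif(n_ev, 1, config$duration_s - 1))
    ev_phase <- rvonmises(n_ev, config$sync_pref_phase,
                          config$sync_theta_kappa)
    ev_time <- vapply(seq_len(n_ev), function(k) {
      snap_to_phase(ev_t0[k], ev_phase[k], phase_img, fs)
    }, numeric(1))
    ok <- !is.na(ev_time) & ev_time > 0.5 &
      ev_time < config$duration_s - 0.5
    if (config$ripple_suppression && nrow(ripples) > 0) {
      pad <- tibble::tibble(start_s = ripples$start_s - 0.05,
                            end_s = ripples$end_s + 0.05)
      ok <- ok & !in_intervals(ev_time, pad)
    }
    ev_time <- ev_time[ok]
    n_ev <- length(ev_time)

    part_sets <- vector("list", n_ev)
    for (k in seq_len(n_ev)) {
      if (config$field_sync_anticorr) {
        asm <- (k - 1L) %% 2L + 1L
        member <- which(assemblies == asm)
        p_in <- min(1, config$participation_p * config$n_cells /
                      length(member))
        part <- member[stats::runif(length(member)) < p_in]
      } else {
        part <- which(stats::runif(config$n_cells) < config$participation_p)
      }
      part_sets[[k]] <- part
    }

    half_w <- config$sync_window_ms / 1000 / 2
    spikes <- vector("list", config$n_cells)
    for (ci in seq_len(config$n_cells)) {
      lam <- base[ci] * state_mult * phase_mod
      if (!is.na(centers[ci])) {
        d <- abs(pos - centers[ci])
        d <- pmin(d, config$track_cm - d)
        field <- exp(-d^2 / (2 * config$field_sigma_cm^2))
        lam <- lam * ifelse(loco_mask, 0.3 + 2.7 * field, 1)
      }
      if (config$ripple_suppression) lam[in_ripple] <- 0
      p <- pmin(lam / fs, 1)
      bg <- (which(stats::runif(n) < p) - 1L) / fs
      sync_t <- numeric(0)
      for (k in seq_len(n_ev)) {
        if (ci %in% part_sets[[k]]) {
          sync_t <- c(sync_t, ev_time[k] + stats::runif(1, -half_w, half_w))
        }
      }
      # refractory merge, sync spikes win conflicts
      if (length(sync_t) > 0) {
        keep_bg <- vapply(bg, function(tt) {
          all(abs(tt - sync_t) > 0.002)
        }, logical(1))
        bg <- bg[keep_bg]
      }
      st <- sort(c(bg, sync_t))
      if (length(st) > 1) {
        keep <- c(TRUE, diff(st) > 0.002)
        st <- st[keep]
      }
      spikes[[ci]] <- st
    }
    names(spikes) <- ids

    # record realized participants (those with a spike near the event)
    parts <- lapply(seq_len(n_ev), function(k) {
      ids[vapply(seq_len(config$n_cells), function(ci) {
        any(abs(spikes[[ci]] - ev_time[k]) <= half_w)
      }, logical(1))]
    })
    true_sync_events <- tibble::tibble(event_time_s = ev_time,
                                       participants = parts)
    list(true_spikes = spikes,
         true_sync_events = true_sync_events,
         true_fields = tibble::tibble(cell_id = ids, center_cm = centers),
         assemblies = assemblies)
  })
}

# Place a candidate time at the nearest moment (same theta cycle) where the
# wrapped phase equals `target_phase`; linear interpolation on the phase grid.
snap_to_phase <- function(t0, target_phase, phase, fs) {
  i0 <- min(max(align_indices(t0, fs) + 1L, 2L), length(phase) - 1L)
  # walk to the enclosing cycle: find previous and next ascending 0-crossing
  lo <- i0
  steps <- as.integer(fs)  # at most 1 s of search
  while (lo > 1L && !(phase[lo] >= 0 && phase[lo - 1L] < 0 &&
                      phase[lo] - phase[lo - 1L] < pi) && i0 - lo < steps) {
    lo <- lo - 1L
  }
  hi <- i0 + 1L
  while (hi < length(phase) && !(phase[hi] >= 0 && phase[hi - 1L] < 0 &&
                                 phase[hi] - phase[hi - 1L] < pi) &&
         hi - i0 < steps) {
    hi <- hi + 1L
  }
  if (lo <= 1L || hi >= length(phase)) return(NA_real_)
  u <- phase[lo:(hi - 1L)]
  u[u < 0] <- u[u < 0] + 2 * pi
  if (any(diff(u) <= 0)) return(NA_real_)
  tgt <- if (target_phase < 0) target_phase + 2 * pi else target_phase
  tgt <- min(max(tgt, u[1]), u[length(u)])
  tt <- (lo:(hi - 1L) - 1L) / fs
  stats::approx(u, tt, xout = tgt, ties = "ordered")$y
}

#' Render raw fluorescence from ground truth
#'
#' The true subVm of each cell mixes a small number of spatially smooth,
#' independently amplitude-modulated theta sources (weights decaying with
#' centroid distance from each source's center, giving distance-dependent
#' coherence), independent slow noise, and a depolarizing bump at each sync
#' event. Spikes add a biexponential transient (~1 ms FWHM). The sensor is
#' negative-going: `raw = F_base * exp(-t/tau) * (1 - dff_true) + white
#' noise`.
#'
#' @param config a `generator_config`.
#' @param truth spike truth from [generate_spikes()].
#' @param lfp_truth list from [generate_lfp()].
#' @param centroids n x 2 matrix of ROI centroids (um).
#' @param seed RNG seed.
#' @return list with `raw_f` (list per cell), `true_subvm` (list per cell).
#' @export
render_fluorescence <- function(config, truth, lfp_truth, centroids,
                                seed = derive_seed(config$seed, 4)) {
  fs <- config$imaging_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  ratio <- as.integer(round(config$lfp_rate_hz / fs))
  phase_img <- lfp_truth$true_theta_phase[seq(1L, length.out = n, by = ratio)]
  with_seed(seed, {
    # spatial theta sources: Gaussian weight fields, independent envelopes
    k_src <- 3L
    src_xy <- cbind(stats::runif(k_src, 0, 1400), stats::runif(k_src, 0, 1200))
    length_um <- 400
    wts <- vapply(seq_len(k_src), function(k) {
      d2 <- (centroids[, 1] - src_xy[k, 1])^2 +
        (centroids[, 2] - src_xy[k, 2])^2
      exp(-d2 / (2 * length_um^2))
    }, numeric(nrow(centroids)))
    wts <- wts / pmax(rowSums(wts), 1e-12)
    src_env <- vapply(seq_len(k_src), function(k) {
      e <- 1 + 0.5 * lowpass_filtfilt(stats::rnorm(n), 2, fs, order = 2) *
        sqrt(fs / 4)
      pmax(e, 0.1)
    }, numeric(n))
    src_phase_off <- stats::runif(k_src, -0.6, 0.6)
    src_sig <- vapply(seq_len(k_src), function(k) {
      src_env[, k] * cos(phase_img + src_phase_off[k])
    }, numeric(n))

    # spike kernel: biexponential, FWHM ~ spike_fwhm_ms, unit peak
    tau_r <- config$spike_fwhm_ms / 1000 / 4
    tau_d <- config$spike_fwhm_ms / 1000 / 0.693   # decay half-time = FWHM
    tk <- seq(0, 0.006, by = 1 / fs)
    kern <- exp(-tk / tau_d) - exp(-tk / tau_r)
    kern <- kern / max(kern)
    kern_peak <- which.max(kern) - 1L   # align sampled peak to the spike time

    ev_idx <- align_indices(truth$true_sync_events$event_time_s, fs) + 1L
    bump_hw <- as.integer(round(0.03 * fs))
    bump <- exp(-seq(-bump_hw, bump_hw)^2 / (2 * (0.010 * fs)^2))

    raw_f <- vector("list", length(truth$true_spikes))
    true_subvm <- vector("list", length(truth$true_spikes))
    tgrid <- (seq_len(n) - 1L) / fs
    bleach <- exp(-tgrid / config$bleach_tau_s)
    for (ci in seq_along(truth$true_spikes)) {
      theta_i <- config$subvm_theta_amp *
        as.numeric(src_sig %*% wts[ci, ])
      slow_noise <- config$subvm_noise_sd *
        lowpass_filtfilt(stats::rnorm(n), 15, fs, order = 2) * sqrt(fs / 30)
      sv <- theta_i + slow_noise
      for (ei in ev_idx) {
        a <- max(1L, ei - bump_hw); b <- min(n, ei + bump_hw)
        sv[a:b] <- sv[a:b] +
          config$sync_bump_amp * bump[(a - ei + bump_hw + 1L):(b - ei + bump_hw + 1L)]
      }
      dff_true <- sv
      si <- align_indices(truth$true_spikes[[ci]], fs) + 1L - kern_peak
      for (s0 in si) {
        a <- max(1L, s0)
        b <- min(n, s0 + length(kern) - 1L)
        dff_true[a:b] <- dff_true[a:b] +
          config$spike_amp * kern[(a - s0 + 1L):(b - s0 + 1L)]
      }
      f_base <- 1000
      raw_f[[ci]] <- f_base * bleach * (1 - dff_true) +
        stats::rnorm(n, 0, config$noise_sd * f_base)
      true_subvm[[ci]] <- sv
    }
    names(raw_f) <- names(truth$true_spikes)
    names(true_subvm) <- names(truth$true_spikes)
    list(raw_f = raw_f, true_subvm = true_subvm)
  })
}

# Uniform centroids in the 1.4 x 1.2 mm field of view with >= 70 um spacing.
place_centroids <- function(n_cells, seed) {
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pts) < n_cells && tries < 10000L) {
      cand <- c(stats::runif(1, 0, 1400), stats::runif(1, 0, 1200))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= 70) {
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1L
    }
    unname(pts)
  })
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes [generate_behavior()], [generate_lfp()], [generate_spikes()] and
#' [render_fluorescence()] into a `session_bundle` plus a ground-truth ledger
#' sufficient to score every detector without re-deriving the truth.
#'
#' @param config a `generator_config`.
#' @return list with `bundle` (a `session_bundle`) and `truth` (list:
#'   `true_spikes`, `true_sync_events`, `true_fields`, `true_theta_phase`,
#'   `true_ripples`, `state_schedule`, `true_subvm`, `centroids`).
#' @export
generate_session <- function(config) {
  beh <- generate_behavior(config)
  lfp <- generate_lfp(config, beh$state_schedule)
  spk <- generate_spikes(config, beh, lfp)
  centroids <- place_centroids(config$n_cells, derive_seed(config$seed, 5))
  flu <- render_fluorescence(config, spk, lfp, centroids)
  cells <- lapply(seq_len(config$n_cells), function(ci) {
    cell_trace(names(flu$raw_f)[ci], flu$raw_f[[ci]], centroids[ci, ],
               config$imaging_rate_hz)
  })
  bundle <- session_bundle(
    cells = cells, lfp = lfp$lfp, behavior = beh$behavior,
    session_id = sprintf("synthetic-%d", config$seed),
    duration_s = config$duration_s, track_length_cm = config$track_cm)
  truth <- list(
    true_spikes = spk$true_spikes,
    true_sync_events = spk$true_sync_events,
    true_fields = spk$true_fields,
    true_theta_phase = lfp$true_theta_phase,
    true_ripples = lfp$true_ripples,
    state_schedule = beh$state_schedule,
    true_subvm = flu$true_subvm,
    centroids = centroids,
    assemblies = spk$assemblies
  )
  list(bundle = bundle, truth = truth)
}
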
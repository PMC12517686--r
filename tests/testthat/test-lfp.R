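# pink background + optional ripple bursts, for detector tests
make_lfp <- function(dur = 20, fs = 8000, bursts = NULL, amp_sd = 8,
                     seed = 1) {
  withr::with_seed(seed, {
    x <- 100 * voltsync:::pink_noise(dur * fs)
    band <- voltsync:::bandpass_filtfilt(x, c(120, 240), fs, 4)
    sdb <- sd(band)
    if (!is.null(bursts)) {
      for (k in seq_len(nrow(bursts))) {
        cc <- bursts$center[k]; dd <- bursts$dur[k]
        i0 <- round((cc - dd / 2) * fs) + 1
        i1 <- round((cc + dd / 2) * fs)
        m <- i1 - i0 + 1
        env <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
        x[i0:i1] <- x[i0:i1] + amp_sd * sdb * env *
          sin(2 * pi * 160 * seq(0, m - 1) / fs)
      }
    }
    x
  })
}

test_that("ripple detector finds injected bursts and rejects short ones", {
  bursts <- data.frame(center = c(5, 12), dur = c(0.06, 0.07))
  x <- make_lfp(bursts = bursts, amp_sd = 8)
  rip <- detect_ripples(x, 8000)
  expect_equal(nrow(rip), 2)
  expect_lt(max(abs(rip$peak_s - bursts$center)), 0.005)
  expect_true(all(rip$duration_ms >= 30))

  # the duration rule: the same burst is kept at min 30 ms and rejected
  # when the minimum duration exceeds its envelope extent
  x2 <- make_lfp(bursts = data.frame(center = 8, dur = 0.06), amp_sd = 8,
                 seed = 2)
  kept <- detect_ripples(x2, 8000)
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(detect_ripples(x2, 8000,
                                   min_duration_ms = kept$duration_ms + 20)),
               0)

  # pure theta is out of band
  th <- 200 * cos(2 * pi * 8 * (seq_len(160000) - 1) / 8000)
  expect_equal(nrow(detect_ripples(th, 8000)), 0)

  expect_error(detect_ripples(rep(1, 16000), 8000), "degenerate")
})

test_that("ripple modulation index is the normalized in/out rate contrast", {
  rip <- tibble::tibble(start_s = c(10, 50, 90), end_s = c(10.05, 50.05, 90.05))
  # zero in-ripple spikes, positive elsewhere: exactly -1
  spk <- setdiff(seq(0.5, 179.5, by = 0.33), numeric(0))
  spk <- spk[!voltsync:::in_intervals(spk, rip)]
  m <- ripple_modulation_index(spk, rip, 180, n_shuffles = 50, seed = 1)
  expect_identical(m$index, -1)

  # exact rate constructions: spikes kept strictly in/out of the intervals
  mk_train <- function(n_per_ripple, r_out) {
    inside <- unlist(lapply(seq_len(nrow(rip)), function(i) {
      seq(rip$start_s[i] + 0.002, rip$end_s[i] - 0.002,
          length.out = n_per_ripple)
    }))
    outside <- seq(0.5, 179.5, length.out = round(r_out * (180 - 0.15)))
    outside <- outside[!voltsync:::in_intervals(outside, rip)]
    sort(c(inside, outside))
  }
  # r_in = r_out = 20 Hz -> 0 (1 spike per 0.05 s interval = 20 Hz)
  t20 <- mk_train(1, 20)
  n_out20 <- sum(!voltsync:::in_intervals(t20, rip))
  m0 <- ripple_modulation_index(t20, rip, 180, 50, 1)
  expect_equal(m0$index, (20 - n_out20 / 179.85) / (20 + n_out20 / 179.85),
               tolerance = 1e-10)
  expect_equal(m0$index, 0, tolerance = 0.01)
  # r_in = 3 x r_out: index = 0.5
  m5 <- ripple_modulation_index(mk_train(3, 20), rip, 180, 20, 1)
  expect_equal(m5$index, 0.5, tolerance = 0.01)
  # antisymmetry: swapping in/out rates flips the sign
  i1 <- ripple_modulation_index(mk_train(2, 10), rip, 180, 20, 1)$index
  i2 <- ripple_modulation_index(mk_train(1, 80), rip, 180, 20, 1)$index
  expect_equal(i1, (40 - 10) / 50, tolerance = 0.01)
  expect_equal(i2, (20 - 80) / 100, tolerance = 0.01)
  expect_true(abs(i1) <= 1 && abs(i2) <= 1)
})

test_that("co-occurrence percentages count both directions", {
  iv <- tibble::tibble(start_s = c(1, 3, 5, 7), end_s = c(1.5, 3.5, 5.5, 7.5))
  z <- co_occurrence(c(2, 4, 6), iv)
  expect_equal(z$pct_intervals_with_event, 0)
  expect_equal(z$pct_events_in_intervals, 0)
  z2 <- co_occurrence(c(1.2, 3.2, 5.2, 7.2), iv)
  expect_equal(z2$pct_intervals_with_event, 100)
  expect_equal(z2$pct_events_in_intervals, 100)
  iv3 <- tibble::tibble(start_s = 0:11, end_s = 0:11 + 0.5)
  z3 <- co_occurrence(c(0.2, 4.3, 8.1), iv3)
  expect_equal(z3$pct_intervals_with_event, 25)
  z4 <- co_occurrence(numeric(0), iv)
  expect_true(z4$empty_input)
})

test_that("triggered averages align periodic structure and drop edge triggers", {
  fs <- 1000
  t <- (seq_len(30 * fs) - 1) / fs
  x <- cos(2 * pi * 2 * t)
  trig <- seq(2, 28, by = 0.5)  # peaks of the 2 Hz cosine
  ta <- triggered_average(x, trig, fs, 0.4)
  expect_equal(ta$mean[ta$lag_s == 0], 1, tolerance = 1e-6)
  expect_equal(max(ta$mean), 1, tolerance = 1e-6)
  expect_equal(ta$n_dropped, 0)

  ta2 <- triggered_average(x, c(0.1, 15), fs, 1)
  expect_equal(ta2$n_dropped, 1)
  expect_equal(ta2$mean, x[(15 * fs + 1 - fs):(15 * fs + 1 + fs)])
  expect_error(triggered_average(x, 0.1, fs, 1), "no valid trigger")
})

test_that("FFT power spectrum localizes tones and satisfies Parseval", {
  fs <- 2000
  tr <- sin(2 * pi * 8 * (seq_len(2 * fs) - 1) / fs)
  psd <- psd_fft(tr, fs)
  expect_equal(psd$freq_hz[which.max(psd$power)], 8, tolerance = 0.15)
  expect_true(all(psd_fft(rep(0, 100), fs)$power == 0))
  # Parseval on the zero-padded transform
  co <- fft(c(tr, numeric(16384 - length(tr))))
  expect_equal(sum(Mod(co)^2) / 16384, sum(tr^2), tolerance = 1e-6)

  # an 8 Hz tone leaves only leakage in the ripple band
  expect_lt(ripple_band_power(psd) / sum(psd$power), 1e-4)
  tr2 <- sin(2 * pi * 160 * (seq_len(2 * fs) - 1) / fs)
  psd2 <- psd_fft(tr2, fs)
  expect_gt(ripple_band_power(psd2) / sum(psd2$power), 0.99)
})

test_that("phase series uses the peak-zero convention", {
  fs <- 2000
  t <- (seq_len(10 * fs) - 1) / fs
  x <- cos(2 * pi * 8 * t)
  ps <- phase_series(x, c(4, 12), fs)
  mid <- 2000:18000
  expect_lt(sd(ps$amp[mid]), 0.02)
  # phase 0 at signal peaks
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[peaks > 2000 & peaks < 18000]
  expect_lt(max(abs(ps$phi[peaks])), 0.05)

  # amplitude tracks a slow modulation envelope
  env <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  ps2 <- phase_series(env * x, c(4, 12), fs)
  expect_gt(cor(ps2$amp[mid], env[mid]), 0.99)

  expect_error(phase_series(x, c(4, 1200), fs), "outside")
})

test_that("event phase modulation follows the vector-sum definition", {
  fs <- 2000
  t <- (seq_len(60 * fs) - 1) / fs
  ps <- phase_series(cos(2 * pi * 8 * t), c(4, 12), fs)
  # events all at the same phase: strength 1 at that phase
  peaks_t <- seq(1, 59, by = 1 / 8)
  m1 <- event_phase_modulation(peaks_t + 1 / 32, ps, n_shuffles = 100, seed = 1)
  expect_equal(m1$strength, 1, tolerance = 0.01)
  expect_equal(m1$preferred_phase, pi / 2, tolerance = 0.1)
  expect_lt(m1$p_value, 0.05)

  # two antipodal events cancel
  m2 <- event_phase_modulation(c(10, 10 + 1 / 16), ps, n_shuffles = 50, seed = 2)
  expect_lt(m2$strength, 0.05)

  # uniform events: weak and nonsignificant
  withr::with_seed(3, ev_u <- runif(800, 1, 59))
  m3 <- event_phase_modulation(ev_u, ps, n_shuffles = 200, seed = 3)
  expect_lt(m3$strength, 0.1)
  expect_gt(m3$p_value, 0.05)

  # global phase rotation leaves strength invariant, rotates the preferred phase
  x2 <- cos(2 * pi * 8 * t - pi / 3)
  ps_rot <- phase_series(x2, c(4, 12), fs)
  m4 <- event_phase_modulation(peaks_t + 1 / 32, ps_rot, n_shuffles = 50,
                               seed = 4)
  expect_equal(m4$strength, m1$strength, tolerance = 0.01)
  # delaying the oscillation by pi/3 advances the phase read at fixed times
  expect_equal(voltsync:::wrap_pi(m4$preferred_phase - m1$preferred_phase),
               -pi / 3, tolerance = 0.1)
})

test_that("phase-deviation histograms concentrate von Mises locked events", {
  fs <- 2000
  t <- (seq_len(120 * fs) - 1) / fs
  ps <- phase_series(cos(2 * pi * 8 * t), c(4, 12), fs)
  withr::with_seed(5, {
    phases <- voltsync:::rvonmises(600, 0, 4)
    # place events at times whose phase matches each draw (phase = 2 pi f t)
    ev <- (phases %% (2 * pi)) / (2 * pi * 8) + sample(8:100 * 8, 600, TRUE) / 8
  })
  h <- phase_deviation_histogram(ev, ps, 0)
  dev <- attr(h, "deviation_deg")
  expect_gte(mean(abs(dev) <= 30), 0.6)   # von Mises kappa=4 concentration
  expect_equal(sum(h$n), 600)

  # all events at the preferred phase fall in the central bin
  h0 <- phase_deviation_histogram(seq(10, 20, by = 1 / 8) + 1e-4, ps, 0)
  expect_equal(sum(h0$n[abs(h0$bin_center_deg) < 15]), sum(h0$n))
})
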
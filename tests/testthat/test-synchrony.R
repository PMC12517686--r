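test_that("sliding counts match the half-open 25 ms window definition", {
  fs <- 2000
  # one spike occupies exactly one window-width of samples
  cts <- sliding_counts(list(1.0), 2, fs, window_ms = 25)
  expect_equal(sum(cts > 0), 50)
  expect_true(all(cts %in% c(0, 1)))

  # N cells spiking together give count N at the event sample
  ctsN <- sliding_counts(replicate(7, 0.5, simplify = FALSE), 1, fs)
  expect_equal(max(ctsN), 7)

  # Poisson trains: mean count ~ total rate x window
  withr::with_seed(1, trains <- poisson_trains(10, 4, 120))
  ctsP <- sliding_counts(trains, 120, fs)
  expect_equal(mean(ctsP), 40 * 0.025, tolerance = 0.05)
})

test_that("jitter surrogates preserve rates and are seed-reproducible", {
  fs <- 2000
  z <- jitter_surrogates(list(numeric(0)), 2, fs, n = 10, seed = 1)
  expect_true(all(z$mean == 0) && all(z$sd == 0))

  withr::with_seed(2, trains <- poisson_trains(8, 5, 60))
  s1 <- jitter_surrogates(trains, 60, fs, n = 50, seed = 42)
  s2 <- jitter_surrogates(trains, 60, fs, n = 50, seed = 42)
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$sd, s2$sd)

  # stationary trains: surrogate mean ~ original mean count
  cts <- sliding_counts(trains, 60, fs)
  expect_equal(mean(s1$mean), mean(cts), tolerance = 0.02)
})

test_that("detect_events finds injected ensembles and is order-invariant", {
  fs <- 2000
  dur <- 120
  withr::with_seed(3, {
    trains <- poisson_trains(14, 3, dur)
    ev <- sort(runif(round(dur), 2, dur - 2))   # ~1 Hz of ensemble events
    ev <- ev[c(TRUE, diff(ev) > 0.5)]
    trains <- inject_ensembles(trains, ev, p = 0.6)
  })
  names(trains) <- sprintf("c%02d", seq_along(trains))
  counts <- sliding_counts(trains, dur, fs)
  sur <- jitter_surrogates(trains, dur, fs, n = 100, seed = 7)
  sync <- detect_events(counts, sur, trains, fs)
  m <- voltsync:::match_events(sync$events$event_time_s, ev, 0.0125)
  expect_gte(m$recall, 0.9)
  med <- median(sync$events$ensemble_size_pct)
  expect_gt(med, 40)

  # given the same counts and surrogates, detection is invariant to cell order
  sync_rev <- detect_events(counts, sur, rev(trains), fs)
  expect_equal(sync_rev$events$event_time_s, sync$events$event_time_s)
  expect_equal(sync_rev$events$ensemble_size_pct,
               sync$events$ensemble_size_pct)

  # all-zero trains give zero events
  s0 <- detect_synchrony(list(numeric(0), numeric(0)), 10, fs,
                         n_jitters = 10, seed = 1)
  expect_equal(nrow(s0$events), 0)
})

test_that("event rates per segment conserve the event count", {
  ev <- list(events = tibble::tibble(event_time_s = seq(1, 179, by = 2)))
  class(ev) <- "sync_events"
  r <- event_rate_segments(ev, 180, 2)
  expect_equal(r$rate_hz, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(r$n_events), 90)

  ev2 <- list(events = tibble::tibble(event_time_s = runif(30, 0, 80)))
  class(ev2) <- "sync_events"
  r2 <- event_rate_segments(ev2, 180, 2)
  expect_equal(r2$n_events, c(30L, 0L))
  r3 <- event_rate_segments(ev2, 180, 5)
  expect_equal(sum(r3$rate_hz * (r3$end_s - r3$start_s)), 30)
})

test_that("burst removal keeps initiating spikes only", {
  expect_equal(remove_burst_spikes(seq(0, 1, by = 0.1)), seq(0, 1, by = 0.1))
  expect_equal(remove_burst_spikes(c(0, 0.005, 0.009)), 0)
  expect_equal(remove_burst_spikes(numeric(0)), numeric(0))
  # 10 ms boundary is exclusive for "burst"
  expect_equal(remove_burst_spikes(c(0, 0.011)), c(0, 0.011))
})

test_that("theta-cycle shuffle preserves phases and spike counts", {
  fs <- 2000
  t <- (seq_len(20 * fs) - 1) / fs
  ph <- voltsync:::wrap_pi(2 * pi * 8 * t)
  withr::with_seed(4, st <- sort(runif(200, 0.5, 19.5)))
  sh <- theta_cycle_shuffle(st, ph, fs, seed = 9)
  expect_equal(length(sh), length(st))
  ph_orig <- ph[align_indices(st, fs) + 1]
  ph_shuf <- ph[align_indices(sh, fs) + 1]
  # phase preserved within one sample of phase re-inversion
  dphi <- abs(voltsync:::wrap_pi(sort(ph_orig) - sort(ph_shuf)))
  expect_lt(median(dphi), 2 * pi * 8 / fs * 1.5)

  # a single-cycle session shuffles to itself
  ph1 <- voltsync:::wrap_pi(2 * pi * 8 * t[1:(fs / 8)])
  st1 <- c(0.01, 0.05)
  expect_equal(theta_cycle_shuffle(st1, ph1, fs, seed = 1), st1)
})

test_that("cycle shuffling reduces the detected synchrony rate on
           ensemble-coordinated data", {
  gs <- default_session()
  fs <- 2000
  trains <- gs$truth$true_spikes
  phase_img <- gs$truth$true_theta_phase[seq(1, length.out = 180 * fs, by = 4)]
  sync <- detect_synchrony(trains, 180, fs, n_jitters = 100, seed = 21)
  shuf <- lapply(seq_along(trains), function(i) {
    theta_cycle_shuffle(trains[[i]], phase_img, fs, seed = 300 + i)
  })
  sync_s <- detect_synchrony(shuf, 180, fs, n_jitters = 100, seed = 22)
  expect_lt(nrow(sync_s$events), 0.7 * nrow(sync$events))
})

test_that("jittering preserves per-cell spike counts exactly", {
  withr::with_seed(5, trains <- poisson_trains(5, 4, 30))
  jt <- jitter_trains(trains, 30)
  expect_identical(lengths(jt), lengths(trains))
  expect_true(all(unlist(jt) >= 0 & unlist(jt) < 30))
})
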
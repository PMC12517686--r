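test_that("segment labels follow the 90% speed rule", {
  fs <- 2000
  segs <- label_segments(rep(5, 10 * fs), fs)
  expect_true(all(segs$state == "locomotion"))
  expect_equal(diff(segs$start_s), rep(0.5, nrow(segs) - 1))

  expect_true(all(label_segments(rep(2, 5 * fs), fs)$state == "excluded"))

  # 95% still + 5% moving: immobility
  sp <- rep(0, 2 * fs)
  sp[1:(0.05 * fs)] <- 5
  s3 <- label_segments(sp, fs)
  expect_identical(s3$state[2], "immobility")
  # exactly 90% is not "more than 90%"
  sp2 <- rep(0, fs); sp2[1:(0.1 * fs)] <- 5
  expect_identical(label_segments(sp2, fs)$state[1], "excluded")
})

test_that("synchrony-triggered subVm aligns theta and drops spiking cells", {
  fs <- 2000
  t <- (seq_len(60 * fs) - 1) / fs
  sv <- 0.01 * cos(2 * pi * 8 * t)
  events <- seq(2, 58, by = 1 / 8)  # at cosine peaks
  out <- synchrony_triggered_subvm(
    list(a = sv, b = sv), list(a = numeric(0), b = 30.06), events, fs)
  # spikeless cell: clean 8 Hz oscillation with a maximum at lag 0
  # (side peaks at whole theta periods are equal by construction)
  tra <- out$per_cell$mean_trace[[which(out$per_cell$cell_id == "a")]]
  expect_equal(tra[601], max(tra), tolerance = 1e-9)
  expect_equal(max(tra), 0.01, tolerance = 1e-3)
  # cell b spiked inside some windows: those are dropped, not the cell
  expect_lt(out$per_cell$n_segments[out$per_cell$cell_id == "b"],
            out$per_cell$n_segments[out$per_cell$cell_id == "a"])

  # a cell spiking in every window is omitted from the grand mean
  dense_spikes <- seq(0.05, 59.95, by = 0.05)
  out2 <- synchrony_triggered_subvm(list(a = sv, c = sv),
                                    list(a = numeric(0), c = dense_spikes),
                                    events, fs)
  expect_identical(out2$omitted, "c")

  # uniform random events: flat mean
  withr::with_seed(1, ev_u <- runif(400, 1, 59))
  out3 <- synchrony_triggered_subvm(list(a = sv), list(a = numeric(0)),
                                    ev_u, fs)
  expect_lt(diff(range(out3$grand_mean)), 0.01 * 3 / sqrt(400) * 6)
})

test_that("spike-triggered subVm respects the minimum-trigger rule", {
  fs <- 2000
  t <- (seq_len(30 * fs) - 1) / fs
  sv <- 0.01 * cos(2 * pi * 8 * t)
  cats <- list(few = seq(2, 2.5, by = 1 / 8)[1:4],
               many = seq(5, 25, by = 1 / 8))
  out <- spike_triggered_subvm(sv, cats, fs)
  expect_false("few" %in% out$category)       # 4 triggers: excluded
  tr <- out$mean_trace[[which(out$category == "many")]]
  expect_equal(tr[601], max(tr), tolerance = 1e-9)
  expect_error(spike_triggered_subvm(sv, list(few = c(1, 2)), fs),
               "excluded")
})

test_that("spike phase modulation separates locked from uniform categories", {
  fs <- 2000
  t <- (seq_len(60 * fs) - 1) / fs
  sv <- 0.01 * cos(2 * pi * 8 * t)
  ps <- phase_series(sv, c(4, 12), fs)
  withr::with_seed(2, {
    locked <- seq(2, 58, by = 1 / 8) + rnorm(449, 0, 0.002)
    uniform <- runif(400, 1, 59)
  })
  out <- spike_phase_modulation(list(locked = locked, uniform = uniform), ps,
                                n_shuffles = 100, seed = 3)
  expect_gt(out$strength[out$category == "locked"], 0.9)
  expect_lt(out$p_value[out$category == "locked"], 0.05)
  expect_lt(out$strength[out$category == "uniform"], 0.15)
  expect_gt(out$p_value[out$category == "uniform"], 0.05)
  # empty categories are skipped
  out2 <- spike_phase_modulation(list(x = numeric(0), locked = locked), ps,
                                 n_shuffles = 50, seed = 4)
  expect_identical(out2$category, "locked")
})

test_that("pairwise subVm cross-correlation has unit self-peak and signed lag", {
  fs <- 2000
  withr::with_seed(3, {
    n <- 30 * fs
    t <- (seq_len(n) - 1) / fs
    shared <- cos(2 * pi * 8 * t)
    a <- shared + 0.5 * rnorm(n)
  })
  segs <- label_segments(rep(5, n), fs)
  xa <- pairwise_subvm_xcorr(a, a, segs, fs)
  expect_equal(xa$peak[1], 1, tolerance = 1e-9)
  expect_equal(xa$peak_lag_ms[1], 0)

  # b = a delayed by 25 ms: positive lag means b lags a
  lagn <- 0.025 * fs
  b <- c(rep(0, lagn), a[1:(n - lagn)])
  xab <- pairwise_subvm_xcorr(a, b, segs, fs)
  expect_equal(xab$peak_lag_ms[1], 25, tolerance = 1)

  # independent noises decorrelate
  withr::with_seed(4, b2 <- rnorm(n))
  x0 <- pairwise_subvm_xcorr(rnorm(n), b2, segs, fs)
  expect_lt(max(abs(x0$xcorr[[1]])), 0.1)
})

test_that("theta coherence is calibrated on shared-signal constructions", {
  fs <- 2000
  n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  segs <- label_segments(rep(5, n), fs)
  withr::with_seed(5, {
    shared <- cos(2 * pi * 8 * t + 0.3 * sin(2 * pi * 0.2 * t))
    na_ <- rnorm(n); nb_ <- rnorm(n)
  })
  # identical traces: coherence exactly 1
  c_same <- pairwise_theta_coherence(shared + 0.1 * na_, shared + 0.1 * na_,
                                     segs, fs)
  expect_equal(c_same$theta_coherence[1], 1, tolerance = 1e-9)

  # shared theta + independent noise at matched in-band power: coherence ~0.5
  sigma <- sqrt(fs / (2 * 8)) / sqrt(2)  # in-band noise power = tone power / ...
  a <- shared + 1 * na_ * 2.2
  b <- shared + 1 * nb_ * 2.2
  c_half <- pairwise_theta_coherence(a, b, segs, fs)
  expect_gt(c_half$theta_coherence[1], 0.2)
  expect_lt(c_half$theta_coherence[1], 0.8)

  # independent noise: near the estimator's bias floor, well below shared case
  c_null <- pairwise_theta_coherence(na_, nb_, segs, fs)
  expect_lt(c_null$theta_coherence[1], 0.45)
  expect_lt(c_null$theta_coherence[1], c_half$theta_coherence[1])
  # bounded in [0, 1]
  expect_true(all(c(c_same$theta_coherence, c_half$theta_coherence,
                    c_null$theta_coherence) >= 0))
  expect_true(all(c(c_same$theta_coherence, c_half$theta_coherence,
                    c_null$theta_coherence) <= 1))
})

test_that("coherence-distance association is rank-based", {
  d <- c(100, 200, 300, 400, 500)
  coh <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  out <- coherence_vs_distance(coh, d)
  expect_equal(out$rho, -1)
  expect_error(coherence_vs_distance(rep(0.5, 5), d), "ties")
})
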
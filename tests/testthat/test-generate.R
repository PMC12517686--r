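test_that("the generator is deterministic under its seed", {
  cfg <- generator_config(seed = 11, duration_s = 30)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1$bundle$cells[[1]]$raw_f, g2$bundle$cells[[1]]$raw_f)
  expect_identical(g1$bundle$lfp$samples, g2$bundle$lfp$samples)
  expect_identical(g1$truth$true_spikes, g2$truth$true_spikes)
  expect_identical(g1$truth$true_sync_events$event_time_s,
                   g2$truth$true_sync_events$event_time_s)
})

test_that("behavior matches the target state fractions and running speed", {
  gs <- default_session()
  sched <- gs$truth$state_schedule
  fr <- vapply(split(sched$end_s - sched$start_s, sched$state), sum,
               numeric(1)) / gs$bundle$duration_s
  expect_lte(abs(100 * fr[["locomotion"]] - 53), 10)
  expect_lte(abs(100 * fr[["immobility"]] - 36), 10)
  sp <- gs$bundle$behavior$speed_cm_s
  expect_lte(abs(mean(sp[sp > 3]) - 8.3), 1.5)
  expect_true(all(gs$bundle$behavior$position_cm >= 0 &
                    gs$bundle$behavior$position_cm <= 90))
})

test_that("LFP theta is state-dependent and ripples are immobility-only", {
  cfg <- generator_config(seed = 13, ripple_rate_immo_hz = 0.15)
  gs <- generate_session(cfg)
  sched <- gs$truth$state_schedule
  immo <- sched[sched$state == "immobility", c("start_s", "end_s")]
  tr <- gs$truth$true_ripples
  expect_gt(nrow(tr), 0)
  expect_true(all(voltsync:::in_intervals(tr$center_s, immo)))

  # locomotion theta peaks above immobility theta
  fs <- gs$bundle$lfp$sampling_rate_hz
  peak_freq <- function(iv) {
    i0 <- round(iv$start_s * fs) + 1
    seg <- gs$bundle$lfp$samples[i0:(i0 + 2 * fs - 1)]
    psd <- psd_fft(seg - mean(seg), fs)
    sel <- psd$freq_hz >= 4 & psd$freq_hz <= 12
    psd$freq_hz[sel][which.max(psd$power[sel])]
  }
  loco <- sched[sched$state == "locomotion", ]
  loco <- loco[loco$end_s - loco$start_s > 2.5, ]
  immo2 <- immo[immo$end_s - immo$start_s > 2.5, ]
  f_loco <- mean(vapply(seq_len(min(4, nrow(loco))),
                        function(i) peak_freq(loco[i, ]), numeric(1)))
  f_immo <- mean(vapply(seq_len(min(4, nrow(immo2))),
                        function(i) peak_freq(immo2[i, ]), numeric(1)))
  expect_gt(f_loco, f_immo)
  expect_equal(f_loco, 8, tolerance = 0.1)
  expect_equal(f_immo, 7, tolerance = 0.1)
})

test_that("spike statistics match the configured population structure", {
  gs <- default_session()
  rates <- vapply(gs$truth$true_spikes, length, numeric(1)) / 180
  expect_gte(median(rates), 2)
  expect_lte(median(rates), 4.5)
  # refractoriness
  isis <- unlist(lapply(gs$truth$true_spikes, function(st) diff(st)))
  expect_true(all(isis > 0.002 - 1e-12))
  # ledger invariant: every participant spikes within the sync window
  ev <- gs$truth$true_sync_events
  ok <- vapply(seq_len(nrow(ev)), function(k) {
    all(vapply(ev$participants[[k]], function(id) {
      any(abs(gs$truth$true_spikes[[id]] - ev$event_time_s[k]) <= 0.0125)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
  # event phases are locked near the configured preferred phase
  fs <- 2000
  ph <- gs$truth$true_theta_phase[seq(1, length.out = 180 * fs, by = 4)]
  evp <- ph[align_indices(ev$event_time_s, fs) + 1]
  strength <- Mod(mean(exp(1i * evp)))
  expect_gt(strength, 0.7)
})

test_that("ripple suppression silences spiking inside true ripples", {
  cfg <- generator_config(seed = 13, ripple_rate_immo_hz = 0.15)
  gs <- generate_session(cfg)
  rip <- gs$truth$true_ripples[, c("start_s", "end_s")]
  n_in <- sum(vapply(gs$truth$true_spikes, function(st) {
    sum(voltsync:::in_intervals(st, rip))
  }, numeric(1)))
  expect_equal(n_in, 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(seed = 1, n_cells = 3, participation_p = 0.3),
               "infeasible")
  expect_error(generator_config(n_cells = 14), "seed")
})

test_that("default sessions pass QC with at least nine analyzable cells", {
  pre <- default_preprocess()
  expect_true(pre$qc$analyzable)
  expect_gte(length(pre$qc$included), 9)
})

test_that("rendered subVm correlates with the generator's truth", {
  gs <- default_session()
  pre <- default_preprocess()
  rs <- vapply(names(gs$truth$true_subvm), function(id) {
    cor(pre$activities[[id]]$subvm, gs$truth$true_subvm[[id]])
  }, numeric(1))
  expect_gt(min(rs), 0.75)
  expect_gt(median(rs), 0.85)
})
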
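# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# Full default session (the study conditions: 14 cells, 180 s, 2 kHz).
default_session <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- generate_session(generator_config(seed = 7))
  }
  .fixtures$default
}

default_preprocess <- function() {
  if (is.null(.fixtures$default_pre)) {
    .fixtures$default_pre <- preprocess_session(default_session()$bundle)
  }
  .fixtures$default_pre
}

# Short session for cheap end-to-end tests.
small_session <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_session(
      generator_config(seed = 3, duration_s = 60, ripple_rate_immo_hz = 0.1))
  }
  .fixtures$small
}

# Homogeneous Poisson spike train on [0, duration).
poisson_train <- function(rate_hz, duration_s) {
  sort(stats::runif(stats::rpois(1, rate_hz * duration_s), 0, duration_s))
}

# n independent Poisson trains.
poisson_trains <- function(n, rate_hz, duration_s) {
  replicate(n, poisson_train(rate_hz, duration_s), simplify = FALSE)
}

# Inject ensemble events into spike trains: at each event time a subset of
# cells fires once within +/-co_halfwidth_s. With exact = TRUE the subset is
# a fixed fraction p of cells (random identity); otherwise Bernoulli(p).
inject_ensembles <- function(trains, event_times, p, co_halfwidth_s = 0.005,
                             exact = FALSE) {
  for (tt in event_times) {
    part <- if (exact) {
      sample.int(length(trains), round(p * length(trains)))
    } else {
      which(stats::runif(length(trains)) < p)
    }
    for (ci in part) {
      trains[[ci]] <- sort(c(trains[[ci]],
                             tt + stats::runif(1, -co_halfwidth_s,
                                               co_halfwidth_s)))
    }
  }
  trains
}

# Uniform jitter of every spike, clipped to the session.
jitter_trains <- function(trains, duration_s, halfwidth_s = 0.075) {
  lapply(trains, function(st) {
    sort(pmin(pmax(st + stats::runif(length(st), -halfwidth_s, halfwidth_s),
                   0), duration_s - 1e-9))
  })
}
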
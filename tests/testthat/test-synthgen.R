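# Simulated-EEG generator: source waveforms, mixing, averaging, ground truth.

test_that("pulse envelopes peak at the configured centers with unit amplitude", {
  cfg <- simulation_config(freq_jitter_hz = 0, pulse_center_jitter_ms = 0)
  set.seed(1)
  S <- make_sources(cfg)
  env <- attr(S, "envelopes")
  expect_equal(dim(env), c(3L, 1000L))
  # Pulses for sources 4-6 are centered at 800, 500, 200 ms (0-based samples).
  expect_equal(which.max(env[1, ]) - 1L, 800L)
  expect_equal(which.max(env[2, ]) - 1L, 500L)
  expect_equal(which.max(env[3, ]) - 1L, 200L)
  expect_equal(max(env), 1, tolerance = 1e-12)
  # sigma = duration/6: the envelope is down to ~1.1% at +-150 ms.
  expect_lt(env[3, 200 + 150 + 1], 0.012)
  # Peak signal amplitude is the sine amplitude (0.5).
  expect_lt(max(abs(S[4:6, ])), 0.5 + 1e-12)
})

test_that("source 1 is unit-variance white noise within Monte-Carlo error", {
  cfg <- simulation_config()
  set.seed(42)
  draws <- replicate(50, make_sources(cfg)[1, ])
  expect_lt(abs(mean(draws)), 0.02)
  expect_equal(stats::var(as.vector(draws)), 1, tolerance = 0.02)
})

test_that("zero-jitter chirps sweep 10->30 Hz by the analytic-signal oracle", {
  cfg <- simulation_config(freq_jitter_hz = 0, pulse_center_jitter_ms = 0)
  set.seed(3)
  S <- make_sources(cfg)
  # FFT-based analytic signal; instantaneous frequency = phase derivative.
  inst_freq <- function(x, srate) {
    n <- length(x)
    X <- stats::fft(x)
    h <- rep(0, n)
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
    a <- stats::fft(X * h, inverse = TRUE) / n
    ph <- unwrap_phase(Arg(a))
    diff(ph) * srate / (2 * pi)
  }
  unwrap_phase <- function(p) {
    dp <- diff(p)
    dp <- dp - 2 * pi * round(dp / (2 * pi))
    cumsum(c(p[1], dp))
  }
  f2 <- inst_freq(S[2, ], 1000)
  # Edge effects of the discrete analytic signal: read slightly inside.
  expect_equal(mean(f2[10:30]), 10, tolerance = 1)
  expect_equal(mean(f2[970:990]), 30, tolerance = 1)
  f3 <- inst_freq(S[3, ], 1000)
  expect_equal(mean(f3[10:30]), 30, tolerance = 1)
  expect_equal(mean(f3[970:990]), 10, tolerance = 1)
})

test_that("pulse sines keep their nominal frequencies without jitter", {
  cfg <- simulation_config(freq_jitter_hz = 0, pulse_center_jitter_ms = 0)
  set.seed(9)
  S <- make_sources(cfg)
  # Periodogram argmax inside each pulse's active 300 ms window; the window
  # length makes the nominal frequencies exact bin centers.
  peak_freq <- function(x, srate) {
    spec <- Mod(stats::fft(x))^2
    k <- which.max(spec[2:(length(x) / 2)])
    k * srate / length(x)
  }
  active <- list(`30` = 651:950, `20` = 351:650, `10` = 51:350)
  for (f in names(active)) {
    src <- 4L + which(c(30, 20, 10) == as.numeric(f)) - 1L
    expect_equal(peak_freq(S[src, active[[f]]], 1000), as.numeric(f),
                 tolerance = 1)
  }
})

test_that("ground-truth labels tile the trial into the five designed states", {
  cfg <- simulation_config()
  labels <- ground_truth_labels(cfg)
  expect_equal(labels[1], 1L) # sample 0
  expect_equal(labels[1000], 5L) # sample 999
  expect_equal(as.integer(table(labels)), c(50L, 300L, 300L, 300L, 50L))
  expect_equal(length(rle(labels)$lengths), 5L)
  # Truth depends only on the nominal design, not the random streams.
  cfg2 <- simulation_config(mixing_seed = 77L, trial_seed = 88L)
  expect_identical(ground_truth_labels(cfg2), labels)
})

test_that("datasets mix, average and reproduce deterministically", {
  cfg <- simulation_config(n_trials = 5L)
  sim <- simulate_eeg(cfg)
  expect_equal(dim(sim$record$data), c(6L, 1000L))
  expect_identical(sim$truth, ground_truth_labels(cfg))

  # Identity mixing with a single trial returns that trial's sources.
  cfg1 <- simulation_config(n_trials = 1L, freq_jitter_hz = 0,
                            pulse_center_jitter_ms = 0)
  sim1 <- simulate_eeg(cfg1, mixing = diag(6), keep_sources = TRUE)
  expect_equal(sim1$record$data, unclass(sim1$sources[[1]]),
               ignore_attr = TRUE)

  # Same seeds give bit-identical output; different trial seeds differ.
  simA <- simulate_eeg(cfg)
  expect_identical(simA$record$data, sim$record$data)
  simB <- simulate_eeg(simulation_config(n_trials = 5L, trial_seed = 99L))
  expect_false(identical(simB$record$data, sim$record$data))
  # The mixing stream is independent of the trial stream.
  expect_identical(simB$mixing, sim$mixing)
})

test_that("trial averaging shrinks the noise variance by ~1/n_trials", {
  cfg <- simulation_config(n_trials = 50L)
  sim <- simulate_eeg(cfg, mixing = diag(6))
  # Channel 1 under identity mixing is the averaged white noise.
  expect_equal(stats::var(sim$record$data[1, ]), 1 / 50, tolerance = 0.35)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_channels = 4), "6")
  expect_error(simulation_config(freq_jitter_hz = 20), "jitter")
  expect_error(simulation_config(duration_ms = -5), "positive")
  expect_error(simulate_eeg(simulation_config(), mixing = diag(3)),
               "n_channels")
})
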
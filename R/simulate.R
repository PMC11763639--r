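#' Configuration for the simulated-EEG generator
#'
#' Defines a synthetic cognitive-task recording built from six designed neural
#' sources: Gaussian white background noise, two crossing linear chirps
#' (frequency-modulated activity), and three Gaussian-pulse-modulated sine
#' waves (amplitude-modulated activity peaking early, mid, and late).  Sources
#' are mixed by a random square matrix (instantaneous linear mixing, emulating
#' volume conduction) and many trials are averaged, as in event-related
#' designs.  The timeline is tiled by five ground-truth microstates S1-S5.
#'
#' Per-trial randomness: chirp endpoint frequencies, sine frequencies, and
#' pulse centers are jittered uniformly within +/- their jitter ranges; the
#' pulse-modulated sines additionally draw a uniform random initial phase.
#'
#' @param n_channels Number of channels; equals the number of sources (square
#'   mixing).
#' @param duration_ms Trial duration in milliseconds.
#' @param srate_hz Sampling rate in Hz.
#' @param n_trials Number of trials averaged into the final recording.
#' @param chirp_f_low,chirp_f_high Chirp sweep endpoints in Hz (source 2
#'   sweeps low to high, source 3 high to low).
#' @param freq_jitter_hz Uniform jitter half-width applied to every nominal
#'   frequency (chirp endpoints and sine frequencies), in Hz.
#' @param pulse_centers_ms Nominal Gaussian-pulse centers for sources 4-6, ms.
#' @param pulse_center_jitter_ms Uniform jitter half-width for pulse centers.
#' @param pulse_duration_ms Gaussian pulse duration, ms.  The pulse standard
#'   deviation is `pulse_duration_ms / 6` so ~99.7% of the pulse mass lies
#'   within the stated duration.
#' @param pulse_peak_amp Peak amplitude of the Gaussian envelope.
#' @param sine_amp Amplitude of the modulated sine waves.
#' @param sine_freqs_hz Nominal sine frequencies for sources 4-6, Hz.
#' @param mixing_seed,trial_seed Seeds for the two independent random streams
#'   (mixing matrix vs per-trial source parameters), so several datasets can
#'   share a mixing matrix while varying trial randomness.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_channels = 6L,
                              duration_ms = 1000L,
                              srate_hz = 1000L,
                              n_trials = 50L,
                              chirp_f_low = 10,
                              chirp_f_high = 30,
                              freq_jitter_hz = 5,
                              pulse_centers_ms = c(800, 500, 200),
                              pulse_center_jitter_ms = 50,
                              pulse_duration_ms = 300,
                              pulse_peak_amp = 1,
                              sine_amp = 0.5,
                              sine_freqs_hz = c(30, 20, 10),
                              mixing_seed = 1L,
                              trial_seed = 2L) {
  cfg <- list(
    n_channels = as.integer(n_channels), duration_ms = as.integer(duration_ms),
    srate_hz = as.integer(srate_hz), n_trials = as.integer(n_trials),
    chirp_f_low = chirp_f_low, chirp_f_high = chirp_f_high,
    freq_jitter_hz = freq_jitter_hz, pulse_centers_ms = pulse_centers_ms,
    pulse_center_jitter_ms = pulse_center_jitter_ms,
    pulse_duration_ms = pulse_duration_ms, pulse_peak_amp = pulse_peak_amp,
    sine_amp = sine_amp, sine_freqs_hz = sine_freqs_hz,
    mixing_seed = as.integer(mixing_seed), trial_seed = as.integer(trial_seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_channels != 6L)
    stop("the generator defines exactly 6 sources; n_channels must be 6",
         call. = FALSE)
  if (cfg$duration_ms <= 0 || cfg$srate_hz <= 0 || cfg$n_trials <= 0)
    stop("durations, sampling rate and trial count must be positive",
         call. = FALSE)
  if (any(c(cfg$chirp_f_low, cfg$chirp_f_high, cfg$sine_freqs_hz) <= 0))
    stop("all frequencies must be positive", call. = FALSE)
  if (length(cfg$pulse_centers_ms) != 3L || length(cfg$sine_freqs_hz) != 3L)
    stop("three pulse centers and three sine frequencies are required",
         call. = FALSE)
  if (cfg$freq_jitter_hz < 0 || cfg$pulse_center_jitter_ms < 0)
    stop("jitters must be nonnegative", call. = FALSE)
  if (cfg$freq_jitter_hz >= min(cfg$chirp_f_low, cfg$sine_freqs_hz) ||
      cfg$pulse_center_jitter_ms >= min(cfg$pulse_centers_ms))
    stop("jitters must be smaller than their nominal values", call. = FALSE)
  invisible(cfg)
}

jit <- function(half_width) if (half_width > 0) runif(1, -half_width, half_width) else 0

#' Generate one trial of the six designed neural sources
#'
#' Draws per-trial randomness from the current RNG state; callers that need
#' reproducibility seed the RNG (as [simulate_eeg()] does via `trial_seed`).
#'
#' @param config A [simulation_config()].
#' @return A 6 x samples matrix: row 1 white noise; rows 2-3 the rising and
#'   falling chirps; rows 4-6 Gaussian-pulse-modulated sines.
#' @export
make_sources <- function(config) {
  validate_simulation_config(config)
  n_samp <- round(config$duration_ms * config$srate_hz / 1000)
  tt <- (seq_len(n_samp) - 1) / config$srate_hz # seconds
  dur <- config$duration_ms / 1000
  S <- matrix(0, nrow = 6L, ncol = n_samp)

  S[1L, ] <- rnorm(n_samp)

  # Linear chirps: phase(t) = 2*pi*(f0 t + (f1-f0)/(2T) t^2) + phi, unit
  # amplitude, random initial phase per trial (like every other per-trial
  # source parameter, so trial averaging is incoherent).
  chirp <- function(f0, f1) {
    sin(2 * pi * (f0 * tt + (f1 - f0) / (2 * dur) * tt^2) +
          runif(1, 0, 2 * pi))
  }
  S[2L, ] <- chirp(config$chirp_f_low + jit(config$freq_jitter_hz),
                   config$chirp_f_high + jit(config$freq_jitter_hz))
  S[3L, ] <- chirp(config$chirp_f_high + jit(config$freq_jitter_hz),
                   config$chirp_f_low + jit(config$freq_jitter_hz))

  sigma <- config$pulse_duration_ms / 6 / 1000 # seconds
  envelopes <- matrix(0, 3L, n_samp)
  for (k in 1:3) {
    f <- config$sine_freqs_hz[k] + jit(config$freq_jitter_hz)
    ctr <- (config$pulse_centers_ms[k] +
              jit(config$pulse_center_jitter_ms)) / 1000
    phase <- runif(1, 0, 2 * pi)
    env <- config$pulse_peak_amp * exp(-(tt - ctr)^2 / (2 * sigma^2))
    envelopes[k, ] <- env
    S[3L + k, ] <- config$sine_amp * sin(2 * pi * f * tt + phase) * env
  }
  attr(S, "envelopes") <- envelopes
  S
}

#' Per-sample ground-truth microstate labels
#'
#' The five states tile the trial: the three 300 ms pulses centered at
#' 200/500/800 ms cover (50, 950) ms, and the flanks (chirp + noise only) form
#' the first and last states.  Boundaries are at 50, 350, 650 and 950 ms,
#' half-open, on the nominal (unjittered) centers.
#'
#' @param config A [simulation_config()].
#' @return Integer vector of length `samples` with values in 1..5.
#' @export
ground_truth_labels <- function(config) {
  validate_simulation_config(config)
  n_samp <- round(config$duration_ms * config$srate_hz / 1000)
  half <- config$pulse_duration_ms / 2
  ctrs <- sort(config$pulse_centers_ms)
  bounds_ms <- c(ctrs[1] - half, ctrs[1] + half, ctrs[2] + half, ctrs[3] + half)
  bounds <- round(bounds_ms * config$srate_hz / 1000)
  labels <- integer(n_samp)
  idx <- seq_len(n_samp) - 1L # 0-based sample index
  labels[idx < bounds[1]] <- 1L
  labels[idx >= bounds[1] & idx < bounds[2]] <- 2L
  labels[idx >= bounds[2] & idx < bounds[3]] <- 3L
  labels[idx >= bounds[3] & idx < bounds[4]] <- 4L
  labels[idx >= bounds[4]] <- 5L
  labels
}

#' Simulate a trial-averaged EEG recording with known microstate structure
#'
#' Draws one mixing matrix (i.i.d. standard normal entries, redrawn until its
#' condition number is below `max_condition`), generates `n_trials` trials of
#' the six sources, mixes each trial, and averages the mixed trials.
#'
#' @param config A [simulation_config()].
#' @param mixing Either `"random"` (default) or an explicit invertible
#'   `n_channels` x `n_channels` matrix (e.g. `diag(6)` for identity mixing).
#' @param keep_sources Keep the per-trial source matrices in the result.
#' @param max_condition Condition-number bound for accepting a random mixing
#'   matrix.
#' @return A `simulated_eeg` list: `record` (an [eeg_record()]), `mixing`,
#'   `truth` (per-sample labels), `sources` (optional list of trials), and the
#'   echoed `config`.
#' @export
simulate_eeg <- function(config = simulation_config(), mixing = "random",
                         keep_sources = FALSE, max_condition = 1e3) {
  validate_simulation_config(config)
  n <- config$n_channels

  if (is.matrix(mixing)) {
    if (!all(dim(mixing) == c(n, n)))
      stop("mixing matrix must be n_channels x n_channels", call. = FALSE)
    M <- mixing
  } else {
    M <- with_seed(config$mixing_seed, {
      draw <- NULL
      for (i in 1:100) {
        cand <- matrix(rnorm(n * n), n, n)
        if (kappa(cand, exact = TRUE) < max_condition) {
          draw <- cand
          break
        }
      }
      draw
    })
    if (is.null(M))
      stop("failed to draw a well-conditioned mixing matrix in 100 attempts",
           call. = FALSE)
  }

  trials <- with_seed(config$trial_seed, {
    lapply(seq_len(config$n_trials), function(i) make_sources(config))
  })
  n_samp <- ncol(trials[[1L]])
  data <- matrix(0, n, n_samp)
  for (S in trials) data <- data + M %*% S
  data <- data / config$n_trials

  out <- list(
    record = eeg_record(data, srate_hz = config$srate_hz,
                        channel_names = paste0("ch", seq_len(n))),
    mixing = M,
    truth = ground_truth_labels(config),
    sources = if (keep_sources) trials else NULL,
    config = config
  )
  class(out) <- "simulated_eeg"
  out
}

#' @export
print.simulated_eeg <- function(x, ...) {
  cat(sprintf(
    "simulated_eeg: %d channels x %d samples at %d Hz (%d trials averaged)\n",
    nrow(x$record$data), ncol(x$record$data), x$config$srate_hz,
    x$config$n_trials))
  cat(sprintf("ground truth: %d states, run lengths %s\n",
              length(unique(x$truth)),
              paste(rle(x$truth)$lengths, collapse = ", ")))
  invisible(x)
}
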
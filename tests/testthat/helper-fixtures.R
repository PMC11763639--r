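# Shared fixtures, built lazily and memoized so expensive objects (a default
# simulated dataset and its distance matrices) are computed once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Random SPD matrix of size n (well conditioned).
rand_spd <- function(n, jitter = 1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + jitter * diag(n)
}

fixture_sim <- function() {
  memo("sim", function() simulate_eeg(simulation_config(
    mixing_seed = 11L, trial_seed = 12L)))
}

fixture_covset <- function() {
  memo("covset", function() {
    sim <- fixture_sim()
    scm_set(segment(sim$record, t = 200L, s = 1L))
  })
}

fixture_distances <- function() {
  memo("distances", function() pairwise_distances_both(fixture_covset()))
}

# Small templated covariance set: two groups of SPD matrices tightly
# clustered around two distant templates.
fixture_two_template_covset <- function(m_per = 6L, n = 4L, seed = 7L) {
  spade:::with_seed(seed, {
    t1 <- rand_spd(n)
    t2 <- 40 * rand_spd(n)
    mats <- c(
      lapply(seq_len(m_per), function(i) t1 + 0.01 * rand_spd(n, 0)),
      lapply(seq_len(m_per), function(i) t2 + 0.01 * rand_spd(n, 0)))
    arr <- array(0, c(n, n, 2L * m_per))
    for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
    structure(list(matrices = arr, gamma = 0, starts = seq_along(mats) - 1L,
                   t = 50L, s = 1L, srate_hz = 1000),
              class = "scm_set")
  })
}
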
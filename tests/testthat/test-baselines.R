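# The six baseline clustering algorithms.

test_that("GFP microstates label every sample by its nearest peak's cluster", {
  # Two alternating topographies with clear amplitude peaks.
  set.seed(1)
  T_total <- 400L
  topoA <- c(3, -3, 1, -1)
  topoB <- c(-1, 1, 3, -3)
  X <- matrix(0, 4, T_total)
  carrier <- abs(sin(2 * pi * (1:T_total) / 40)) + 0.05
  block <- rep(rep(c(1, 2), each = 100), length.out = T_total)
  for (p in seq_len(T_total))
    X[, p] <- (if (block[p] == 1) topoA else topoB) * carrier[p] +
      0.01 * rnorm(4)
  rec <- eeg_record(X, srate_hz = 1000)
  res <- gfp_microstates(rec, s = 2L, seed = 1L)
  expect_length(res$labels, T_total)
  expect_true(all(res$labels %in% 1:2))
  expect_gt(ari(res$labels, block), 0.9)

  # Constant signal: no strict GFP maxima.
  recc <- eeg_record(matrix(rep(c(1, -1), 50), 2), srate_hz = 100)
  expect_error(gfp_microstates(recc, s = 2L), "maxima")

  # Reproducibility.
  res2 <- gfp_microstates(rec, s = 2L, seed = 1L)
  expect_identical(res$labels, res2$labels)
})

test_that("the GMM baseline recovers well-separated mixtures by monotone EM", {
  set.seed(2)
  X <- rbind(matrix(rnorm(200 * 3), ncol = 3),
             matrix(rnorm(200 * 3, mean = 7), ncol = 3))
  rec <- eeg_record(t(X), srate_hz = 100)
  res <- gmm_cluster(rec, s = 2L, seed = 1L)
  expect_equal(ari(res$labels, rep(1:2, each = 200)), 1)
  expect_true(all(diff(res$loglik) > -1e-6 * abs(res$loglik[1])))

  res1 <- gmm_cluster(rec, s = 1L, seed = 1L)
  expect_equal(length(unique(res1$labels)), 1L)

  res2 <- gmm_cluster(rec, s = 2L, seed = 1L)
  expect_identical(res$labels, res2$labels)
})

test_that("soft-DTW obeys the divergence convention and its gradient is exact", {
  set.seed(3)
  x <- matrix(rnorm(30), 15, 2)
  y <- matrix(rnorm(30), 15, 2)
  # Divergence of a segment with itself is zero by construction.
  vxx <- spade:::cpp_softdtw(x, x, 1.0)
  expect_equal(vxx - 0.5 * vxx - 0.5 * vxx, 0)
  # sdtw(x, y) >= mean of self terms fails in general, but symmetry holds.
  expect_equal(spade:::cpp_softdtw(x, y, 1.0), spade:::cpp_softdtw(y, x, 1.0),
               tolerance = 1e-10)
  # Analytic gradient against central differences.
  g <- spade:::cpp_softdtw_grad(x, y, 0.7)
  for (idx in list(c(1, 1), c(8, 2), c(15, 1))) {
    eps <- 1e-5
    xp <- x; xp[idx[1], idx[2]] <- xp[idx[1], idx[2]] + eps
    xm <- x; xm[idx[1], idx[2]] <- xm[idx[1], idx[2]] - eps
    num <- (spade:::cpp_softdtw(xp, y, 0.7) -
              spade:::cpp_softdtw(xm, y, 0.7)) / (2 * eps)
    expect_equal(g$grad[idx[1], idx[2]], num, tolerance = 1e-6)
  }
})

test_that("soft-DTW K-means co-clusters duplicated templates", {
  set.seed(4)
  tmpl <- lapply(1:3, function(k) matrix(rnorm(60), 6, 10))
  segs <- array(0, c(6, 10, 30))
  for (i in 1:30)
    segs[, , i] <- tmpl[[(i - 1) %% 3 + 1]] + 0.01 * matrix(rnorm(60), 6, 10)
  ss <- structure(list(segments = segs, starts = 0:29, t = 10L, s = 1L,
                       srate_hz = 100), class = "segment_set")
  res <- softdtw_cluster(ss, s = 3L, seed = 1L)
  expect_equal(ari(res$labels, rep(1:3, 10)), 1)
  res2 <- softdtw_cluster(ss, s = 3L, seed = 1L)
  expect_identical(res$labels, res2$labels)
})

test_that("SCM vectorization has n(n+1)/2 entries and feeds K-means", {
  covset <- fixture_two_template_covset(n = 4L)
  expect_equal(ncol(spade:::vectorize_scms(covset)), 10L)
  # Widths for the 6- and 28-channel cases.
  expect_equal(6L * 7L / 2L, 21L)
  expect_equal(28L * 29L / 2L, 406L)
  cs6 <- structure(list(matrices = array(diag(6), c(6, 6, 2)), gamma = 0),
                   class = "scm_set")
  expect_equal(ncol(spade:::vectorize_scms(cs6)), 21L)

  res <- scm_vector_kmeans(covset, s = 2L, seed = 1L)
  expect_equal(ari(res$labels, rep(1:2, each = 6)), 1)

  # Identical SCMs: a single centroid fits with zero inertia.
  csid <- structure(list(matrices = array(diag(3), c(3, 3, 5)), gamma = 0),
                    class = "scm_set")
  expect_equal(scm_vector_kmeans(csid, s = 1L, seed = 1L)$inertia, 0)
})

test_that("autoencoder K-means separates templated covariance sets", {
  covset <- fixture_two_template_covset()
  spec <- encoder_spec(hidden = c(8L, 4L), latent_dim = 2L,
                       pretrain_epochs = 150L, seed = 2L)
  res <- ae_kmeans(covset, spec, s = 2L)
  expect_equal(ncol(res$Z), 2L)
  expect_equal(ari(res$labels, rep(1:2, each = 6)), 1)
})

test_that("tangent-space K-means maps through the Frechet mean", {
  covset <- fixture_two_template_covset()
  res <- tangent_kmeans(covset, s = 2L, seed = 1L)
  expect_equal(ari(res$labels, rep(1:2, each = 6)), 1)
  expect_equal(ncol(res$tangent), 4L * 5L / 2L)

  # All-identical SCMs give all-zero tangent vectors.
  set.seed(5)
  C <- rand_spd(3)
  csid <- structure(list(matrices = array(rep(C, 6), c(3, 3, 6)), gamma = 0),
                    class = "scm_set")
  tv <- spade:::cpp_tangent_vectors(csid$matrices, C, TRUE, 1e-12)
  expect_lt(max(abs(tv)), 1e-9)
})
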
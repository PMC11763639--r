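# Deep embedded clustering: soft assignments, target distribution,
# autoencoder pretraining, centroid initialization, joint optimization.

make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  spade:::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
    }))
    list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

test_that("soft assignments follow the Student-t kernel", {
  set.seed(1)
  Z <- matrix(rnorm(20 * 3), 20)
  U <- matrix(rnorm(4 * 3), 4)
  Q <- soft_assign(Z, U)
  expect_equal(rowSums(Q), rep(1, 20), tolerance = 1e-12)

  # Scalar hand computation: z = 0 against centroids 0 and 3 with alpha = 1
  # gives kernel weights (1, 1/10).
  q <- soft_assign(matrix(0, 1, 1), matrix(c(0, 3), 2, 1))
  expect_equal(as.numeric(q), c(10 / 11, 1 / 11), tolerance = 1e-12)

  # Equidistant point: uniform assignment.
  qu <- soft_assign(matrix(c(0, 0), 1), rbind(c(1, 0), c(-1, 0), c(0, 1)))
  expect_equal(as.numeric(qu), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("the target distribution sharpens confident assignments", {
  Q1 <- matrix(c(0.8, 0.2), 1)
  expect_equal(target_distribution(Q1), Q1, tolerance = 1e-12)

  Q2 <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  P2 <- target_distribution(Q2)
  expect_equal(rowSums(P2), c(1, 1), tolerance = 1e-12)
  expect_gt(P2[1, 1], 0.9)
  # Hand check of the q^2/f normalization for row 2.
  f <- colSums(Q2)
  w <- Q2[2, ]^2 / f
  expect_equal(P2[2, ], w / sum(w), tolerance = 1e-12)

  expect_warning(target_distribution(rbind(c(1, 0), c(1, 0))), "empty")
})

test_that("KL divergence is nonnegative and zero iff P equals Q", {
  set.seed(2)
  Q <- matrix(runif(12), 4)
  Q <- Q / rowSums(Q)
  expect_equal(spade:::kl_divergence(Q, Q), 0)
  P <- target_distribution(Q)
  expect_gte(spade:::kl_divergence(P, Q), 0)
})

test_that("pretraining reconstructs and embeds reproducibly", {
  blobs <- make_blobs(30, rbind(c(0, 0, 0, 0), c(6, 6, 6, 6)), seed = 3)
  spec <- encoder_spec(hidden = c(8L, 4L), latent_dim = 2L,
                       pretrain_epochs = 150L, seed = 5L)
  pre <- pretrain_autoencoder(blobs$X, spec)
  expect_lt(tail(pre$loss_trace, 1), pre$loss_trace[1])
  pre2 <- pretrain_autoencoder(blobs$X, spec)
  expect_identical(pre$Z, pre2$Z)

  # Constant input rows embed to identical latents with near-zero error
  # (bias-only solution; a few hundred Adam steps get close, not exact).
  Xc <- matrix(1, 40, 6)
  prec <- pretrain_autoencoder(Xc, encoder_spec(
    hidden = c(8L, 4L), latent_dim = 2L, pretrain_epochs = 400L, seed = 5L))
  expect_lt(tail(prec$loss_trace, 1), 0.01)
  expect_lt(max(apply(prec$Z, 2, sd)), 1e-8)

  # Two well-separated blobs stay separable in the latent space.
  d <- as.matrix(dist(pre$Z))
  sil <- riemannian_silhouette(blobs$truth, d)
  expect_gt(sil, 0.5)
})

test_that("centroid initialization follows K-means conventions", {
  set.seed(6)
  Z <- matrix(rnorm(10 * 2), 10)
  U <- init_centroids(Z, s = 10L, seed = 1L)
  expect_equal(dim(U), c(10L, 2L))
  expect_equal(sort(rowSums(U)), sort(rowSums(Z)), tolerance = 1e-10)

  Zdup <- matrix(rep(c(1, 2), each = 6), 6)
  expect_equal(as.numeric(init_centroids(Zdup, 1L, seed = 1L)), c(1, 2))

  blobs <- make_blobs(25, rbind(c(0, 0), c(8, 8)), seed = 7)
  U2 <- init_centroids(blobs$X, 2L, seed = 2L)
  mu <- rbind(colMeans(blobs$X[1:25, ]), colMeans(blobs$X[26:50, ]))
  reorder <- order(U2[, 1])
  expect_equal(U2[reorder, ], mu[order(mu[, 1]), ], tolerance = 0.5,
               ignore_attr = TRUE)

  expect_error(init_centroids(Z, 11L, seed = 1L), "exceed")
})

test_that("DEC recovers well-separated blobs and descends the KL objective", {
  blobs <- make_blobs(40, rbind(c(0, 0, 0), c(7, 0, 7), c(0, 7, -7)),
                      seed = 8)
  spec <- encoder_spec(hidden = c(16L, 8L), latent_dim = 3L,
                       pretrain_epochs = 150L, finetune_iters = 400L,
                       batch_size = 64L, seed = 9L)
  model <- dec_fit(blobs$X, spec, s = 3L)
  expect_equal(ari(model$labels, blobs$truth), 1)
  expect_equal(rowSums(model$Q), rep(1, 120), tolerance = 1e-9)
  expect_equal(model$labels, max.col(model$Q))
  # KL at the last refresh does not exceed the first post-initialization KL.
  expect_lte(tail(model$kl_trace, 1), model$kl_trace[2] + 1e-8)

  model2 <- dec_fit(blobs$X, spec, s = 3L)
  expect_identical(model$labels, model2$labels)

  # Permuting input rows yields the same partition on separable data.
  p <- sample(seq_len(nrow(blobs$X)))
  modelp <- dec_fit(blobs$X[p, ], spec, s = 3L)
  expect_equal(ari(modelp$labels, blobs$truth[p]), 1)
})

test_that("every cluster keeps at least one member on multimodal input", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(5, 5), c(-5, 5), c(5, -5),
                                c(-5, -5)), seed = 10)
  spec <- encoder_spec(hidden = c(16L, 8L), latent_dim = 4L,
                       pretrain_epochs = 150L, finetune_iters = 300L,
                       batch_size = 64L, seed = 11L)
  model <- dec_fit(blobs$X, spec, s = 5L)
  expect_equal(sort(unique(model$labels)), 1:5)
})
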
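# Sensor-space spatial-pattern distance, Riemannian geometry on the SPD
# manifold, and pairwise distance matrices.

test_that("distances of a matrix with itself hit their identity values", {
  set.seed(1)
  C <- rand_spd(4)
  expect_equal(sensor_distance(C, C), 1, tolerance = 1e-10)
  expect_equal(riemannian_distance(C, C), 0, tolerance = 1e-10)
  expect_equal(log_map(C, C), matrix(0, 4, 4), tolerance = 1e-10)
})

test_that("closed forms hold for commuting (diagonal) matrices", {
  Ci <- diag(c(4, 1))
  I2 <- diag(2)
  expect_equal(sensor_distance(Ci, I2, symmetrize = FALSE), 4)
  expect_equal(sensor_distance(Ci, I2), 4)
  # Raw generalized eigenvalue is asymmetric; symmetrization restores >= 1.
  expect_equal(sensor_distance(I2, Ci, symmetrize = FALSE), 1)
  expect_equal(sensor_distance(I2, Ci), 4)
  expect_equal(riemannian_distance(Ci, I2), log(4), tolerance = 1e-12)
})

test_that("the symmetrized sensor distance is >= 1 with equality iff equal", {
  set.seed(2)
  for (i in 1:20) {
    A <- rand_spd(3)
    B <- rand_spd(3)
    expect_gte(sensor_distance(A, B), 1)
  }
  A <- rand_spd(3)
  expect_equal(sensor_distance(A, A + 0 * A), 1, tolerance = 1e-9)
  expect_gt(sensor_distance(A, A + diag(c(1, 0, 0))), 1)
})

test_that("the Riemannian distance is a congruence-invariant metric", {
  set.seed(3)
  for (i in 1:20) {
    A <- rand_spd(3)
    B <- rand_spd(3)
    C <- rand_spd(3)
    M <- matrix(rnorm(9), 3)
    dAB <- riemannian_distance(A, B)
    expect_gte(dAB, 0)
    expect_equal(dAB, riemannian_distance(B, A), tolerance = 1e-10)
    # Affine invariance under congruence by an invertible matrix.
    expect_equal(riemannian_distance(M %*% A %*% t(M), M %*% B %*% t(M)),
                 dAB, tolerance = 1e-8)
    # Triangle inequality.
    expect_lte(dAB,
               riemannian_distance(A, C) + riemannian_distance(C, B) + 1e-8)
  }
})

test_that("sensor and source SCM distances are blind to the mixing matrix", {
  # Source-space covariances pushed through X = M S: C = M N M'.
  set.seed(4)
  Ns <- lapply(1:4, function(i) diag(runif(3, 0.2, 3)))
  M <- matrix(rnorm(9), 3)
  Cs <- lapply(Ns, function(N) M %*% N %*% t(M))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(riemannian_distance(Cs[[i]], Cs[[j]]),
                 riemannian_distance(Ns[[i]], Ns[[j]]), tolerance = 1e-8)
  }
})

test_that("the Frechet mean generalizes the geometric mean", {
  A <- rand_spd(3)
  expect_equal(frechet_mean(list(A)), A)
  expect_equal(frechet_mean(list(A, A, A)), A, tolerance = 1e-8)
  expect_equal(frechet_mean(list(diag(2), diag(c(4, 4)))), diag(c(2, 2)),
               tolerance = 1e-6)
  # Commuting family: elementwise geometric mean of eigenvalues.
  D1 <- diag(c(1, 9))
  D2 <- diag(c(4, 1))
  expect_equal(frechet_mean(list(D1, D2)), diag(c(2, 3)), tolerance = 1e-6)

  # Congruence equivariance.
  set.seed(5)
  Es <- lapply(1:3, function(i) rand_spd(3))
  M <- matrix(rnorm(9), 3)
  lhs <- frechet_mean(lapply(Es, function(E) M %*% E %*% t(M)))
  rhs <- M %*% frechet_mean(Es) %*% t(M)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("non-convergence raises a condition carrying the last iterate", {
  set.seed(6)
  mats <- lapply(1:5, function(i) rand_spd(4))
  err <- tryCatch(frechet_mean(mats, tol = 0, max_iter = 2L),
                  spade_frechet_error = function(e) e)
  expect_s3_class(err, "spade_frechet_error")
  expect_true(is.matrix(err$iterate))
})

test_that("the log map obeys its base-point and norm identities", {
  set.seed(7)
  E <- rand_spd(3)
  C <- rand_spd(3)
  # Identity base point reduces to the matrix logarithm.
  eC <- eigen(C, symmetric = TRUE)
  logmC <- eC$vectors %*% diag(log(eC$values)) %*% t(eC$vectors)
  expect_equal(log_map(diag(3), C), logmC, tolerance = 1e-9)
  # Whitened norm of the tangent image equals the Riemannian distance.
  L <- log_map(E, C)
  expect_equal(L, t(L), tolerance = 1e-9)
  W <- spade:::sym_matfun(E, function(v) 1 / sqrt(v))
  expect_equal(norm(W %*% L %*% W, "F"), riemannian_distance(E, C),
               tolerance = 1e-8)
})

test_that("pairwise matrices match per-pair recomputation and conventions", {
  set.seed(8)
  mats <- lapply(1:5, function(i) rand_spd(3))
  arr <- array(0, c(3, 3, 5))
  for (i in 1:5) arr[, , i] <- mats[[i]]
  Dsen <- pairwise_distances(arr, kind = "sensor")
  Dsrc <- pairwise_distances(arr, kind = "source")
  expect_equal(diag(unclass(Dsen)), rep(1, 5))
  expect_equal(diag(unclass(Dsrc)), rep(0, 5))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(Dsen[i, j], sensor_distance(mats[[i]], mats[[j]]),
                 tolerance = 1e-10)
    expect_equal(Dsrc[i, j], riemannian_distance(mats[[i]], mats[[j]]),
                 tolerance = 1e-10)
  }
  both <- pairwise_distances_both(arr)
  expect_equal(unclass(both$sensor), unclass(Dsen), ignore_attr = TRUE)
  expect_equal(unclass(both$source), unclass(Dsrc), ignore_attr = TRUE)

  # Identical matrices: all-ones sensor block, all-zeros source block.
  arr2 <- array(rep(unlist(mats[1]), 2), c(3, 3, 2))
  expect_equal(unclass(pairwise_distances(arr2, "sensor")),
               matrix(1, 2, 2), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unclass(pairwise_distances(arr2, "source")),
               matrix(0, 2, 2), ignore_attr = TRUE, tolerance = 1e-9)
})
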
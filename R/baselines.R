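# The six baseline clustering algorithms used in the simulation comparison:
# (1) GFP-peak microstates, (2) Gaussian mixture on raw samples, (3) soft-DTW
# K-means on segments, (4) K-means on vectorized SCMs, (5) autoencoder +
# K-means on vectorized SCMs, (6) K-means in the tangent space at the Fréchet
# mean.

#' Global-field-power microstate clustering (per-sample)
#'
#' Computes the GFP (spatial standard deviation across channels per sample),
#' finds its strict local maxima, K-means clusters the scalp topographies at
#' the peaks, and assigns every sample the cluster of its temporally nearest
#' peak (ties to the earlier peak).
#'
#' @param record An [eeg_record()].
#' @param s Number of clusters (must not exceed the number of GFP peaks).
#' @param seed RNG seed for K-means (10 restarts).
#' @param normalize Normalize peak topographies to unit GFP before clustering
#'   (off by default: plain polarity-sensitive K-means on raw topographies).
#' @return List: `labels` (per-sample), `peaks` (1-based peak sample
#'   indices), `gfp`, `peak_labels`.
#' @export
gfp_microstates <- function(record, s = 5L, seed = 1L, normalize = FALSE) {
  X <- record$data
  n <- nrow(X)
  gfp <- sqrt(colMeans(sweep(X, 2L, colMeans(X))^2))
  T_total <- length(gfp)
  inner <- 2:(T_total - 1L)
  is_peak <- gfp[inner] > gfp[inner - 1L] & gfp[inner] > gfp[inner + 1L]
  peaks <- inner[is_peak]
  if (length(peaks) < s)
    stop(sprintf("found %d GFP local maxima but s=%d clusters requested",
                 length(peaks), s), call. = FALSE)
  topo <- t(X[, peaks, drop = FALSE])
  if (normalize) topo <- topo / pmax(gfp[peaks], 1e-12)
  peak_labels <- with_seed(seed, {
    kmeans(topo, centers = s, nstart = 10L, iter.max = 100L)$cluster
  })
  # Nearest peak in time; exact midpoints go to the earlier peak.
  nearest <- vapply(seq_len(T_total), function(p) {
    d <- abs(peaks - p)
    which.min(d) # ties: first (earlier) index
  }, integer(1))
  list(labels = peak_labels[nearest], peaks = peaks, gfp = gfp,
       peak_labels = peak_labels)
}

#' Gaussian-mixture-model clustering of raw samples (per-sample)
#'
#' Treats the T samples as points in channel space and fits a
#' full-covariance Gaussian mixture by EM, initialized from seeded K-means
#' responsibilities; labels are posterior argmax.  Component covariances are
#' ridged by `reg_covar` times the mean per-channel variance to keep the
#' E-step defined when a component collapses; if the fit still degenerates a
#' tenfold-stronger ridge is tried once before erroring.
#'
#' @param record An [eeg_record()].
#' @param s Number of mixture components.
#' @param seed RNG seed.
#' @param reg_covar Relative diagonal ridge added to component covariances.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return List: `labels` (per-sample), `posterior` (T x s), `means`,
#'   `loglik` (per-iteration trace, non-decreasing).
#' @export
gmm_cluster <- function(record, s = 5L, seed = 1L, reg_covar = 1e-6,
                        max_iter = 100L, tol = 1e-6) {
  X <- t(record$data)
  if (nrow(X) <= s) stop("need more samples than clusters", call. = FALSE)
  fit <- with_seed(seed, {
    f <- tryCatch(gmm_em(X, s, reg_covar, max_iter, tol),
                  error = function(e) NULL)
    if (is.null(f))
      f <- tryCatch(gmm_em(X, s, reg_covar * 10, max_iter, tol),
                    error = function(e) NULL)
    f
  })
  if (is.null(fit))
    stop("GMM fit degenerate even with a stronger covariance ridge",
         call. = FALSE)
  list(labels = max.col(fit$post), posterior = fit$post, means = fit$means,
       loglik = fit$loglik)
}

# Full-covariance EM; draws K-means initial responsibilities from the
# current RNG state.
gmm_em <- function(X, s, reg_covar, max_iter, tol) {
  n <- nrow(X)
  d <- ncol(X)
  ridge <- reg_covar * mean(apply(X, 2L, var)) * diag(d)
  km <- kmeans(X, centers = s, nstart = 1L, iter.max = 100L)
  resp <- outer(km$cluster, seq_len(s), "==") * 1

  log_dens <- function(mu, Sigma) {
    ch <- chol(Sigma + ridge)
    Y <- forwardsolve(t(ch), t(X) - mu)
    -0.5 * colSums(Y^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  }

  loglik <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) stop("empty mixture component", call. = FALSE)
    w <- nk / n
    mus <- t(resp) %*% X / nk
    ld <- matrix(0, n, s)
    for (k in seq_len(s)) {
      Xc <- sweep(X, 2L, mus[k, ])
      Sigma <- crossprod(Xc * resp[, k], Xc) / nk[k]
      ld[, k] <- log(w[k]) + log_dens(mus[k, ], Sigma)
    }
    # E step with log-sum-exp
    mx <- apply(ld, 1L, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    if (!all(is.finite(lse))) stop("degenerate component density",
                                   call. = FALSE)
    loglik <- c(loglik, sum(lse))
    resp <- exp(ld - lse)
    if (iter > 1L &&
        abs(loglik[iter] - loglik[iter - 1L]) <
          tol * (abs(loglik[iter - 1L]) + 1))
      break
  }
  list(post = resp, means = mus, loglik = loglik)
}

#' Soft-DTW K-means clustering of segments (per-segment)
#'
#' K-means-style alternation under the soft-DTW divergence
#' `D(x, y) = sdtw(x, y) - (sdtw(x, x) + sdtw(y, y)) / 2` on multichannel
#' segments; barycenters are updated by L-BFGS on the summed soft-DTW
#' objective using the analytic gradient.
#'
#' @param segments A [segment()] result.
#' @param s Number of clusters.
#' @param gamma_smooth Soft-min smoothing parameter.
#' @param seed RNG seed (initial barycenters are sampled segments).
#' @param max_iter Maximum assignment/update alternations.
#' @param barycenter_iters L-BFGS iterations per barycenter update (warm
#'   started across alternations; total per-barycenter work is capped at 50
#'   gradient evaluations).
#' @param label_tol Stop when the fraction of labels changed between
#'   alternations drops below this.
#' @param downsample Keep every `downsample`-th time point of each segment
#'   for the DTW representation (1 = full resolution).  Alignment-based
#'   comparison is robust to moderate temporal decimation, and the dynamic
#'   program's cost falls quadratically with the factor.
#' @return List: `labels` (per-segment), `barycenters`, `converged`.
#' @export
softdtw_cluster <- function(segments, s = 5L, gamma_smooth = 1.0, seed = 1L,
                            max_iter = 8L, barycenter_iters = 2L,
                            label_tol = 0.01, downsample = 1L) {
  segs <- segments$segments # n x t x m
  m <- dim(segs)[3]
  if (m < s) stop("need at least s segments", call. = FALSE)
  # soft-DTW operates on time x channels series.
  cube <- aperm(segs, c(2, 1, 3))
  if (downsample > 1L) {
    keep <- seq(1L, dim(cube)[1], by = as.integer(downsample))
    cube <- cube[keep, , , drop = FALSE]
  }
  self_vals <- as.numeric(cpp_softdtw_self(cube, gamma_smooth))

  with_seed(seed, {
    # kmeans++-style seeding under the soft-DTW divergence.
    seed_idx <- sample.int(m, 1L)
    for (j in seq_len(s - 1L)) {
      cen <- cube[, , seed_idx, drop = FALSE]
      cross0 <- cpp_softdtw_cross(cube, cen, gamma_smooth)
      div0 <- cross0 - 0.5 * outer(self_vals, rep(1, length(seed_idx))) -
        0.5 * outer(rep(1, m), self_vals[seed_idx])
      mind <- pmax(apply(div0, 1L, min), 0)
      if (sum(mind) == 0) mind <- rep(1, m)
      mind[seed_idx] <- 0
      seed_idx <- c(seed_idx, sample.int(m, 1L, prob = mind / sum(mind)))
    }
    centers <- cube[, , seed_idx, drop = FALSE]
    labels <- rep(0L, m)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      cross <- cpp_softdtw_cross(cube, centers, gamma_smooth)
      cself <- as.numeric(cpp_softdtw_self(centers, gamma_smooth))
      div <- cross - 0.5 * outer(self_vals, rep(1, s)) -
        0.5 * outer(rep(1, m), cself)
      new_labels <- max.col(-div, ties.method = "first")
      # Rescue empty clusters with the worst-fit segment.
      for (j in setdiff(seq_len(s), unique(new_labels))) {
        far <- which.max(apply(div, 1L, min))
        new_labels[far] <- j
        div[far, ] <- -Inf
      }
      changed <- mean(new_labels != labels)
      labels <- new_labels
      if (changed < label_tol) {
        converged <- TRUE
        break
      }
      for (j in seq_len(s)) {
        members <- cube[, , labels == j, drop = FALSE]
        b0 <- centers[, , j]
        # fn and gr share one evaluation via a single-slot cache.
        cache <- new.env(parent = emptyenv())
        evaluate <- function(par) {
          if (!identical(cache$par, par)) {
            b <- matrix(par, nrow(b0), ncol(b0))
            cache$res <- cpp_softdtw_barycenter_obj(b, members, gamma_smooth)
            cache$par <- par
          }
          cache$res
        }
        opt <- optim(
          par = as.vector(b0),
          fn = function(par) evaluate(par)$value,
          gr = function(par) as.vector(evaluate(par)$grad),
          method = "L-BFGS-B",
          control = list(maxit = barycenter_iters))
        centers[, , j] <- matrix(opt$par, nrow(b0), ncol(b0))
      }
    }
    if (!converged)
      warning("soft-DTW K-means did not stabilize; returning best-so-far",
              call. = FALSE)
    list(labels = labels, barycenters = centers, converged = converged)
  })
}

# Upper triangle (including diagonal) of each SCM as a row vector.
vectorize_scms <- function(covset, weight_sqrt2 = FALSE) {
  cube <- covset$matrices
  n <- dim(cube)[1]
  m <- dim(cube)[3]
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  w <- matrix(1, n, n)
  if (weight_sqrt2) {
    w[upper.tri(w)] <- sqrt(2)
  }
  out <- matrix(0, m, length(idx))
  for (i in seq_len(m)) out[i, ] <- (cube[, , i] * w)[idx]
  out
}

#' K-means on vectorized SCMs (per-segment)
#'
#' Flattens each SCM to its `n (n + 1) / 2` upper-triangle entries and runs
#' Euclidean K-means with 10 restarts.
#'
#' @param covset An [scm_set()].
#' @param s Number of clusters.
#' @param seed RNG seed.
#' @return List: `labels`, `inertia`, `vectors`.
#' @export
scm_vector_kmeans <- function(covset, s = 5L, seed = 1L) {
  Vm <- vectorize_scms(covset)
  km <- with_seed(seed, kmeans(Vm, centers = s, nstart = 10L, iter.max = 100L))
  list(labels = km$cluster, inertia = km$tot.withinss, vectors = Vm)
}

#' Autoencoder + K-means on vectorized SCMs (per-segment)
#'
#' Flattens the SCMs, column-standardizes, pretrains an autoencoder, and
#' K-means clusters the latent vectors.
#'
#' @param covset An [scm_set()].
#' @param spec An [encoder_spec()] (the seed inside also seeds K-means).
#' @param s Number of clusters.
#' @return List: `labels`, `Z` (latents), `pretrain`.
#' @export
ae_kmeans <- function(covset, spec = encoder_spec(), s = 5L) {
  Vm <- standardize_columns(vectorize_scms(covset))
  pre <- pretrain_autoencoder(Vm, spec)
  km <- with_seed(child_seed(spec$seed, 3L),
                  kmeans(pre$Z, centers = s, nstart = 10L, iter.max = 100L))
  list(labels = km$cluster, Z = pre$Z, pretrain = pre)
}

#' Tangent-space K-means (per-segment)
#'
#' Maps every SCM to the tangent space at the Fréchet mean of the whole set
#' via the logarithm map, vectorizes the symmetric tangent matrices (upper
#' triangle, off-diagonal entries scaled by sqrt(2) so Euclidean inner
#' products match Frobenius inner products), and runs K-means.
#'
#' @param covset An [scm_set()].
#' @param s Number of clusters.
#' @param seed RNG seed.
#' @param weight_sqrt2 Use the Frobenius-preserving sqrt(2) off-diagonal
#'   weighting (plain vectorization available for strict parity with naive
#'   flattening).
#' @return List: `labels`, `mean` (the Fréchet mean), `tangent` (m x p).
#' @export
tangent_kmeans <- function(covset, s = 5L, seed = 1L, weight_sqrt2 = TRUE) {
  cube <- covset$matrices
  E <- frechet_mean(cube)
  tang <- cpp_tangent_vectors(cube, E, weight_sqrt2, 1e-12)
  km <- with_seed(seed, kmeans(tang, centers = s, nstart = 10L,
                               iter.max = 100L))
  list(labels = km$cluster, mean = E, tangent = tang)
}
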
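# Feature construction: classical MDS of the two distance matrices, log
# variance features, per-block standardization, and fusion.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities, `B = -1/2 J (D o D) J`, and
#' embeds the points with the top `dim` eigenpairs, scaling eigenvectors by
#' the square roots of their eigenvalues.  Negative eigenvalues (non-Euclidean
#' dissimilarities) are clipped to zero; a warning is raised only when the
#' clipping affects the requested dimensions, i.e. fewer than `dim`
#' eigenvalues are positive.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param dim Embedding dimension, `1 <= dim <= m - 1`.
#' @param tol Symmetry/diagonal tolerance.
#' @return An m x dim coordinate matrix with attribute `eigenvalues`.
#' @export
classical_mds <- function(D, dim, tol = 1e-8) {
  D <- unclass(D)
  if (!is_square_matrix(D)) stop("`D` must be square", call. = FALSE)
  m <- nrow(D)
  scale_ref <- max(1, max(abs(D)))
  if (max(abs(D - t(D))) > tol * scale_ref)
    stop("`D` must be symmetric", call. = FALSE)
  if (max(abs(diag(D))) > tol * scale_ref)
    stop("`D` must have a zero diagonal", call. = FALSE)
  dim <- as.integer(dim)
  if (dim < 1L || dim > m - 1L)
    stop("`dim` must be in [1, m - 1]", call. = FALSE)

  D2 <- D^2
  # Double centering: B = -1/2 J D2 J with J = I - 11'/m.
  B <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, m)) -
                 outer(rep(1, m), colMeans(D2)) + mean(D2))

  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  scale_ev <- max(abs(ev))
  n_pos <- sum(ev > tol * max(scale_ev, .Machine$double.eps))
  if (n_pos < dim && any(ev < -tol * scale_ev))
    warning(sprintf(
      "only %d positive MDS eigenvalues for %d requested dimensions; remaining coordinates set to zero",
      n_pos, dim), call. = FALSE)
  lam <- pmax(ev[seq_len(dim)], 0)
  # Relative floor: eigenvalues at numerical-noise level (including those of
  # an all-zero dissimilarity matrix) must not survive into coordinates that
  # later standardization would inflate.
  lam[lam <= 1e-10 * scale_ev | lam <= .Machine$double.eps] <- 0
  coords <- e$vectors[, seq_len(dim), drop = FALSE] *
    rep(sqrt(lam), each = m)
  attr(coords, "eigenvalues") <- ev
  coords
}

# Column z-scoring; zero-variance columns map to zeros rather than NaN.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  Z <- sweep(X, 2L, mu)
  keep <- sdev > 0
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2L, sdev[keep], "/")
  Z[, !keep] <- 0
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdev
  Z
}

#' Fuse per-segment features into the m x 3n clustering matrix
#'
#' Three blocks of width n each, z-standardized per column and concatenated:
#' \describe{
#'   \item{logdiag}{log of the SCM diagonals (log channel variances, local
#'     activity).}
#'   \item{mds_sensor}{classical MDS of the elementwise log of the
#'     sensor-space distance matrix.  The log maps the unit diagonal to the
#'     zero diagonal MDS requires and compresses the variance-ratio scale to
#'     one comparable with the Riemannian distances.}
#'   \item{mds_source}{classical MDS of the Riemannian distance matrix.}
#' }
#'
#' @param covset An [scm_set()].
#' @param D_sensor Sensor-space distance matrix from [pairwise_distances()].
#' @param D_source Source-space (Riemannian) distance matrix.
#' @return An m x 3n `spade_features` matrix with attribute `block_slices`.
#' @export
build_features <- function(covset, D_sensor, D_source) {
  cube <- covset$matrices
  n <- dim(cube)[1]
  m <- dim(cube)[3]
  if (!all(dim(D_sensor) == m) || !all(dim(D_source) == m))
    stop("distance matrices must be m x m with m matching `covset`",
         call. = FALSE)

  diags <- t(apply(cube, 3L, diag))
  if (min(diags) <= 0)
    stop("SCM diagonals must be positive for the log transform", call. = FALSE)
  block1 <- log(diags)
  block2 <- classical_mds(log(pmax(unclass(D_sensor), 1)), n)
  block3 <- classical_mds(unclass(D_source), n)

  V <- cbind(standardize_columns(block1),
             standardize_columns(block2),
             standardize_columns(block3))
  colnames(V) <- c(paste0("logvar", seq_len(n)),
                   paste0("mds_sensor", seq_len(n)),
                   paste0("mds_source", seq_len(n)))
  structure(V,
            block_slices = list(logdiag = 1:n, mds_sensor = n + 1:n,
                                mds_source = 2 * n + 1:n),
            class = c("spade_features", "matrix", "array"))
}
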
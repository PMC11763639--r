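# Distances and means on the manifold of symmetric positive definite
# matrices, plus the sensor-space spatial-pattern distance.

#' Spatial-pattern distance in sensor space
#'
#' The largest generalized eigenvalue of `(Ci, Cj)`: the maximal variance
#' ratio achievable by a spatial filter `w` maximizing
#' `(w' Ci w) / (w' Cj w)`.  The raw quantity is asymmetric in its arguments;
#' with `symmetrize = TRUE` (default) the larger of the two orderings is
#' returned, which is `>= 1` with equality iff `Ci == Cj`.
#'
#' @param Ci,Cj SPD matrices of equal size.
#' @param symmetrize Return `max(lambda_max(Ci,Cj), lambda_max(Cj,Ci))`.
#' @param floor_ev Eigenvalue floor for numerical stability.
#' @return A scalar (`>= 1` when symmetrized).
#' @export
sensor_distance <- function(Ci, Cj, symmetrize = TRUE, floor_ev = 1e-12) {
  check_spd(Ci, "Ci")
  check_spd(Cj, "Cj")
  if (!all(dim(Ci) == dim(Cj)))
    stop("`Ci` and `Cj` must have the same size", call. = FALSE)
  W <- sym_matfun(Cj, function(v) 1 / sqrt(v), floor_ev)
  ev <- eigen(W %*% Ci %*% W, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, floor_ev)
  if (symmetrize) max(max(ev), 1 / min(ev)) else max(ev)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta_R(Ci, Cj) = || logm(Ci^{-1/2} Cj Ci^{-1/2}) ||_F`, the geodesic
#' distance under the affine-invariant metric.  It is symmetric, zero iff the
#' arguments are equal, and invariant under congruence `C -> M C M'` for any
#' invertible `M` — hence identical between sensor-space SCMs and the
#' underlying source-space SCMs of a linear mixing model.
#'
#' @inheritParams sensor_distance
#' @return A nonnegative scalar.
#' @export
riemannian_distance <- function(Ci, Cj, floor_ev = 1e-12) {
  check_spd(Ci, "Ci")
  check_spd(Cj, "Cj")
  if (!all(dim(Ci) == dim(Cj)))
    stop("`Ci` and `Cj` must have the same size", call. = FALSE)
  W <- sym_matfun(Ci, function(v) 1 / sqrt(v), floor_ev)
  ev <- eigen(W %*% Cj %*% W, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, floor_ev))^2))
}

#' Fréchet (geometric) mean of a set of SPD matrices
#'
#' The minimizer of the sum of squared Riemannian distances, computed by the
#' Karcher flow: at each iteration the matrices are whitened by the current
#' estimate, their matrix logs averaged, and the estimate moved along the
#' exponential map.  Initialized at the arithmetic mean with unit step.
#'
#' @param mats List of SPD matrices or an n x n x m array.
#' @param tol Convergence threshold on the Frobenius norm of the mean tangent
#'   vector.
#' @param max_iter Maximum Karcher iterations; non-convergence raises an error
#'   whose condition carries the last iterate (`condition$iterate`).
#' @param floor_ev Eigenvalue floor.
#' @return An SPD matrix.
#' @export
frechet_mean <- function(mats, tol = 1e-6, max_iter = 50L, floor_ev = 1e-12) {
  cube <- as_cube(mats)
  m <- dim(cube)[3]
  if (m == 0L) stop("`mats` must be nonempty", call. = FALSE)
  if (m == 1L) return(cube[, , 1])
  res <- cpp_frechet_mean(cube, tol, as.integer(max_iter), floor_ev)
  if (!res$converged) {
    cond <- structure(
      class = c("spade_frechet_error", "error", "condition"),
      list(message = sprintf(
             "Frechet mean did not converge in %d iterations (residual %.3g)",
             max_iter, res$residual),
           call = sys.call(-1), iterate = res$mean))
    stop(cond)
  }
  res$mean
}

#' Logarithm map at a base point
#'
#' `Log_E(C) = E^{1/2} logm(E^{-1/2} C E^{-1/2}) E^{1/2}`: the tangent-space
#' image of `C` at base point `E`, a symmetric matrix.  The whitened norm of
#' the image equals the Riemannian distance `delta_R(E, C)`.
#'
#' @param E SPD base point.
#' @param C SPD matrix to map.
#' @param floor_ev Eigenvalue floor.
#' @return A symmetric matrix.
#' @export
log_map <- function(E, C, floor_ev = 1e-12) {
  check_spd(E, "E")
  check_spd(C, "C")
  Eisq <- sym_matfun(E, function(v) 1 / sqrt(v), floor_ev)
  Esq <- sym_matfun(E, sqrt, floor_ev)
  L <- Esq %*% sym_matfun(Eisq %*% C %*% Eisq, log, floor_ev) %*% Esq
  (L + t(L)) / 2
}

#' Pairwise spatial-pattern distance matrix
#'
#' Computes all `m (m - 1) / 2` pairwise distances between the SCMs of a
#' segment set, in sensor space (symmetrized largest generalized eigenvalue;
#' unit diagonal) or source space (Riemannian distance; zero diagonal).
#'
#' @param covset An [scm_set()] (or list/array of SPD matrices).
#' @param kind `"sensor"` or `"source"`.
#' @param floor_ev Eigenvalue floor.
#' @return A symmetric m x m matrix with attributes `kind` and `symmetrized`,
#'   class `spade_dist`.
#' @export
pairwise_distances <- function(covset, kind = c("source", "sensor"),
                               floor_ev = 1e-12) {
  kind <- match.arg(kind)
  cube <- if (inherits(covset, "scm_set")) covset$matrices else as_cube(covset)
  if (dim(cube)[3] < 2L)
    stop("at least 2 matrices are required", call. = FALSE)
  both <- cpp_pairwise_spd(cube, floor_ev)
  out <- if (kind == "sensor") both$sensor else both$riemann
  distance_matrix(out, kind)
}

#' Both pairwise distance matrices in one pass
#'
#' The sensor- and source-space distances share one eigendecomposition per
#' pair, so computing them together halves the cost of the pipeline's
#' distance step.
#'
#' @inheritParams pairwise_distances
#' @return List with elements `sensor` and `source`, each a `spade_dist`.
#' @export
pairwise_distances_both <- function(covset, floor_ev = 1e-12) {
  cube <- if (inherits(covset, "scm_set")) covset$matrices else as_cube(covset)
  if (dim(cube)[3] < 2L)
    stop("at least 2 matrices are required", call. = FALSE)
  both <- cpp_pairwise_spd(cube, floor_ev)
  list(sensor = distance_matrix(both$sensor, "sensor"),
       source = distance_matrix(both$riemann, "source"))
}

distance_matrix <- function(values, kind) {
  structure(values, kind = kind, symmetrized = TRUE,
            class = c("spade_dist", class(values)))
}

#' @export
print.spade_dist <- function(x, ...) {
  cat(sprintf("spade_dist: %d x %d %s-space distance matrix\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}
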
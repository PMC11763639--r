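# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user scripts.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(stream)) %% 2147483629
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  x
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

check_spd <- function(C, name = "C", tol = 1e-8) {
  if (!is_square_matrix(C))
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  if (max(abs(C - t(C))) > tol * max(1, max(abs(C))))
    stop(sprintf("`%s` is not symmetric", name), call. = FALSE)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("`%s` is not positive definite", name), call. = FALSE)
  invisible(C)
}

# Matrix function of a symmetric matrix via eigendecomposition with an
# eigenvalue floor.
sym_matfun <- function(C, f, floor_ev = 1e-12) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- f(pmax(e$values, floor_ev))
  S <- e$vectors %*% (vals * t(e$vectors))
  (S + t(S)) / 2
}

# expm of a symmetric matrix (no floor: tangent vectors have signed spectra).
sym_expm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  M <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (M + t(M)) / 2
}

as_cube <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3L) return(mats)
  if (is.list(mats)) {
    n <- nrow(mats[[1L]])
    arr <- array(0, dim = c(n, n, length(mats)))
    for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
    return(arr)
  }
  stop("expected a list of matrices or a 3-d array", call. = FALSE)
}
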
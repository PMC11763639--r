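# Deep embedded clustering: a small fully-connected autoencoder trained by
# minibatch Adam, K-means initialization of centroids in the latent space,
# Student-t soft assignments, and KL(P || Q) fine-tuning of encoder and
# centroids jointly.  Sizes here are desk scale (hundreds of segments, tens
# of features), so the network is implemented directly with matrix algebra.

#' Encoder/training specification for deep embedded clustering
#'
#' @param input_dim Width of the input feature vectors (3n for fused
#'   features).
#' @param hidden Integer vector of hidden-layer widths of the encoder; the
#'   decoder mirrors them.
#' @param latent_dim Bottleneck width k (>= 2).  Default 5, matching the
#'   usual deep-embedded-clustering convention of a latent dimension equal to
#'   the expected cluster count.
#' @param activation Hidden-layer activation.  `"tanh"` (default) suits the
#'   z-scored, approximately normal fused features; `"relu"` is available.
#' @param pretrain_epochs Reconstruction-pretraining epochs.
#' @param finetune_iters Maximum KL fine-tuning minibatch steps.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (capped at the number of rows).
#' @param update_interval Steps between refreshes of the target distribution.
#' @param label_change_tol Stop fine-tuning when the fraction of hard labels
#'   changed between refreshes falls below this.
#' @param seed RNG seed controlling initialization and batching.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(input_dim = NULL, hidden = c(32L, 16L),
                         latent_dim = 5L, activation = c("tanh", "relu"),
                         pretrain_epochs = 500L, finetune_iters = 2000L,
                         learning_rate = 1e-3, batch_size = 256L,
                         update_interval = 30L, label_change_tol = 0.001,
                         seed = 1L) {
  activation <- match.arg(activation)
  if (latent_dim < 2L) stop("latent_dim must be >= 2", call. = FALSE)
  if (any(hidden < 1L)) stop("hidden widths must be positive", call. = FALSE)
  if (label_change_tol <= 0 || label_change_tol >= 1)
    stop("label_change_tol must be in (0, 1)", call. = FALSE)
  structure(list(input_dim = input_dim, hidden = as.integer(hidden),
                 latent_dim = as.integer(latent_dim), activation = activation,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_iters = as.integer(finetune_iters),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 update_interval = as.integer(update_interval),
                 label_change_tol = label_change_tol,
                 seed = as.integer(seed)),
            class = "encoder_spec")
}

## ---- minimal MLP machinery ----

act_fun <- function(x, type) switch(type, relu = pmax(x, 0), tanh = tanh(x))
act_grad <- function(pre, type)
  switch(type, relu = (pre > 0) * 1, tanh = 1 - tanh(pre)^2)

# Glorot-uniform initialization; draws from the current RNG state.
mlp_init <- function(widths) {
  layers <- vector("list", length(widths) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- widths[i]
    fan_out <- widths[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[i]] <- list(W = matrix(runif(fan_in * fan_out, -lim, lim),
                                   fan_in, fan_out),
                        b = rep(0, fan_out))
  }
  layers
}

# Forward pass; hidden layers activated, final layer linear.
mlp_forward <- function(layers, X, activation) {
  L <- length(layers)
  pre <- vector("list", L)
  post <- vector("list", L + 1L)
  post[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- post[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    pre[[i]] <- Z
    post[[i + 1L]] <- if (i < L) act_fun(Z, activation) else Z
  }
  list(pre = pre, post = post, out = post[[L + 1L]])
}

# Backward pass given dL/d(output); returns per-layer gradients and dL/dX.
mlp_backward <- function(layers, cache, dOut, activation) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    if (i < L) delta <- delta * act_grad(cache$pre[[i]], activation)
    grads[[i]] <- list(W = crossprod(cache$post[[i]], delta),
                      b = colSums(delta))
    delta <- delta %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

minibatches <- function(m, batch_size) {
  idx <- sample.int(m)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

## ---- autoencoder pretraining ----

#' Pretrain the autoencoder on reconstruction
#'
#' Trains encoder and mirrored decoder end to end with minibatch Adam on the
#' mean squared reconstruction error, then returns the latent representation
#' of every row.
#'
#' @param V Numeric feature matrix (rows = segments).
#' @param spec An [encoder_spec()].
#' @return List: `encoder`, `decoder` (layer lists), `Z` (m x k latents),
#'   `loss_trace` (per-epoch MSE), `activation`.
#' @export
pretrain_autoencoder <- function(V, spec = encoder_spec()) {
  V <- unclass(V)
  m <- nrow(V)
  d <- ncol(V)
  if (!is.null(spec$input_dim) && spec$input_dim != d)
    stop("spec$input_dim does not match ncol(V)", call. = FALSE)
  widths_enc <- c(d, spec$hidden, spec$latent_dim)
  widths_dec <- rev(widths_enc)
  bs <- min(spec$batch_size, m)

  with_seed(spec$seed, {
    enc <- mlp_init(widths_enc)
    dec <- mlp_init(widths_dec)
    st_e <- adam_init(enc)
    st_d <- adam_init(dec)
    loss_trace <- numeric(spec$pretrain_epochs)
    step <- 0L
    for (epoch in seq_len(spec$pretrain_epochs)) {
      tot <- 0
      for (batch in minibatches(m, bs)) {
        Xb <- V[batch, , drop = FALSE]
        fe <- mlp_forward(enc, Xb, spec$activation)
        fd <- mlp_forward(dec, fe$out, spec$activation)
        err <- fd$out - Xb
        tot <- tot + sum(err^2)
        dOut <- 2 * err / (length(batch) * d)
        bd <- mlp_backward(dec, fd, dOut, spec$activation)
        be <- mlp_backward(enc, fe, bd$dX, spec$activation)
        step <- step + 1L
        upd <- adam_update(dec, bd$grads, st_d, spec$learning_rate, step)
        dec <- upd$layers
        st_d <- upd$state
        upe <- adam_update(enc, be$grads, st_e, spec$learning_rate, step)
        enc <- upe$layers
        st_e <- upe$state
      }
      loss_trace[epoch] <- tot / (m * d)
      if (!is.finite(loss_trace[epoch]))
        stop(sprintf("non-finite pretraining loss at epoch %d", epoch),
             call. = FALSE)
    }
    Z <- mlp_forward(enc, V, spec$activation)$out
    list(encoder = enc, decoder = dec, Z = Z, loss_trace = loss_trace,
         activation = spec$activation)
  })
}

#' K-means initialization of latent centroids
#'
#' @param Z m x k latent matrix.
#' @param s Number of clusters (`s <= m`).
#' @param seed RNG seed (10 restarts, best inertia kept).
#' @return s x k centroid matrix.
#' @export
init_centroids <- function(Z, s, seed = 1L) {
  if (s > nrow(Z)) stop("s must not exceed the number of points", call. = FALSE)
  if (s == nrow(Z)) {
    # Each point its own centroid (zero inertia); stats::kmeans requires
    # strictly fewer centers than points.
    U <- as.matrix(Z)
    dimnames(U) <- NULL
    return(U)
  }
  with_seed(seed, {
    km <- kmeans(Z, centers = s, nstart = 10L, iter.max = 100L)
    km$centers
  })
}

#' Student-t soft cluster assignments
#'
#' `q_ij` is proportional to `(1 + ||z_i - u_j||^2 / alpha)^{-(alpha+1)/2}`,
#' normalized over clusters (the kernel of a Student-t with `alpha` degrees
#' of freedom).
#'
#' @param Z m x k latent matrix.
#' @param U s x k centroid matrix.
#' @param alpha Degrees of freedom (default 1).
#' @return m x s row-stochastic matrix.
#' @export
soft_assign <- function(Z, U, alpha = 1) {
  d2 <- outer(rowSums(Z^2), rep(1, nrow(U))) +
    outer(rep(1, nrow(Z)), rowSums(U^2)) - 2 * Z %*% t(U)
  d2 <- pmax(d2, 0)
  num <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  num / rowSums(num)
}

#' Auxiliary target distribution
#'
#' Sharpens the soft assignments: `p_ij = (q_ij^2 / f_j) / sum_j'(...)` with
#' cluster frequencies `f_j = sum_i q_ij`, upweighting confident assignments
#' and normalizing away cluster-size bias.
#'
#' @param Q Row-stochastic soft-assignment matrix.
#' @param eps Guard for empty-cluster columns (`f_j = 0`), with a warning.
#' @return m x s row-stochastic matrix.
#' @export
target_distribution <- function(Q, eps = 1e-12) {
  f <- colSums(Q)
  if (any(f <= 0)) {
    warning("empty cluster column in Q; guarded with eps", call. = FALSE)
    f <- pmax(f, eps)
  }
  W <- sweep(Q^2, 2L, f, "/")
  W / rowSums(W)
}

kl_divergence <- function(P, Q) {
  keep <- P > 0
  sum(P[keep] * log(P[keep] / pmax(Q[keep], 1e-300)))
}

#' Deep embedded clustering of a feature matrix
#'
#' Pretrains the autoencoder, initializes `s` centroids by K-means in the
#' latent space, then jointly fine-tunes encoder weights and centroids by
#' minibatch gradient descent on `KL(P || Q)`, refreshing the target
#' distribution `P` every `update_interval` steps.  Stops early when the
#' fraction of hard labels changed between refreshes drops below
#' `label_change_tol`.  A centroid left empty at a refresh is reseeded at the
#' point with the lowest assignment confidence.
#'
#' @param V Feature matrix (rows = segments), e.g. from [build_features()].
#' @param spec An [encoder_spec()].
#' @param s Number of clusters (>= 2).
#' @param alpha Student-t degrees of freedom.
#' @return A `cluster_model` list: `Z`, `U`, `Q`, `P`, `labels`, `kl_trace`,
#'   `encoder`, `activation`, `pretrain`.
#' @export
dec_fit <- function(V, spec = encoder_spec(), s = 5L, alpha = 1) {
  V <- unclass(V)
  m <- nrow(V)
  s <- as.integer(s)
  if (s < 2L) stop("s must be >= 2", call. = FALSE)
  if (s > m) stop("s must not exceed the number of rows", call. = FALSE)

  pre <- pretrain_autoencoder(V, spec)
  enc <- pre$encoder
  U <- init_centroids(pre$Z, s, seed = child_seed(spec$seed, 1L))

  bs <- min(spec$batch_size, m)
  with_seed(child_seed(spec$seed, 2L), {
    st_e <- adam_init(enc)
    st_u <- list(mU = U * 0, vU = U * 0)
    Z <- mlp_forward(enc, V, spec$activation)$out
    Q <- soft_assign(Z, U, alpha)
    P <- target_distribution(Q)
    labels_prev <- max.col(Q)
    kl_trace <- kl_divergence(P, Q)

    batch_pool <- integer(0)
    it <- 0L
    while (it < spec$finetune_iters) {
      it <- it + 1L

      if (length(batch_pool) == 0L) batch_pool <- sample.int(m)
      take <- seq_len(min(bs, length(batch_pool)))
      batch <- batch_pool[take]
      batch_pool <- batch_pool[-take]

      fe <- mlp_forward(enc, V[batch, , drop = FALSE], spec$activation)
      Zb <- fe$out
      Qb <- soft_assign(Zb, U, alpha)
      Pb <- P[batch, , drop = FALSE]

      # KL gradients (alpha-general DEC form): weight (P - Q) by the
      # Student-t kernel and the latent displacement.
      d2 <- outer(rowSums(Zb^2), rep(1, s)) +
        outer(rep(1, length(batch)), rowSums(U^2)) - 2 * Zb %*% t(U)
      wgt <- ((alpha + 1) / alpha) * (Pb - Qb) / (1 + pmax(d2, 0) / alpha)
      dZ <- (1 / length(batch)) * (rowSums(wgt) * Zb - wgt %*% U)
      dU <- (1 / length(batch)) * (colSums(wgt) * U - t(wgt) %*% Zb)

      be <- mlp_backward(enc, fe, dZ, spec$activation)
      upd <- adam_update(enc, be$grads, st_e, spec$learning_rate, it)
      enc <- upd$layers
      st_e <- upd$state
      # Adam on centroids.
      bc1 <- 1 - 0.9^it
      bc2 <- 1 - 0.999^it
      st_u$mU <- 0.9 * st_u$mU + 0.1 * dU
      st_u$vU <- 0.999 * st_u$vU + 0.001 * dU^2
      U <- U - spec$learning_rate * (st_u$mU / bc1) /
        (sqrt(st_u$vU / bc2) + 1e-8)

      if (it %% spec$update_interval == 0L) {
        Z <- mlp_forward(enc, V, spec$activation)$out
        Q <- soft_assign(Z, U, alpha)
        labels <- max.col(Q)
        # Empty-cluster rescue: reseed at the least-confident point.
        empty <- setdiff(seq_len(s), unique(labels))
        if (length(empty) > 0L) {
          conf_order <- order(apply(Q, 1L, max))
          for (j in seq_along(empty))
            U[empty[j], ] <- Z[conf_order[j], ]
          Q <- soft_assign(Z, U, alpha)
          labels <- max.col(Q)
        }
        P <- target_distribution(Q)
        kl_trace <- c(kl_trace, kl_divergence(P, Q))
        changed <- mean(labels != labels_prev)
        labels_prev <- labels
        if (changed < spec$label_change_tol) break
      }
    }

    Z <- mlp_forward(enc, V, spec$activation)$out
    Q <- soft_assign(Z, U, alpha)
    P <- target_distribution(Q)
    structure(list(Z = Z, U = U, Q = Q, P = P, labels = max.col(Q),
                   kl_trace = kl_trace, encoder = enc,
                   activation = spec$activation, iterations = it,
                   pretrain = pre),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "cluster_model: %d points, %d clusters, latent dim %d (%d DEC steps)\n",
    nrow(x$Z), nrow(x$U), ncol(x$Z), x$iterations))
  cat("cluster sizes:", paste(tabulate(x$labels, nrow(x$U)), collapse = ", "),
      "\n")
  invisible(x)
}
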
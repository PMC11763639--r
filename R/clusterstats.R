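# Statistical validation of a clustering: for every unordered cluster pair,
# sample within-cluster and cross-cluster Riemannian distances and test
# whether the within-cluster distances are significantly smaller.

#' Sample intra- and inter-cluster distance distributions
#'
#' For every unordered pair of clusters, draws `n_pairs` within-cluster
#' element pairs (sampled with replacement, pooled equally over the two
#' clusters when `pool = TRUE`) and `n_pairs` cross-cluster pairs, reading
#' distances from the precomputed matrix.  Cluster pairs involving a
#' singleton cluster are skipped with a warning.
#'
#' @param D m x m distance matrix (e.g. [pairwise_distances()] of kind
#'   `"source"`).
#' @param labels Cluster labels of the m elements.
#' @param n_pairs Sampled pairs per distribution.
#' @param seed RNG seed.
#' @param pool Pool within-cluster samples over both clusters of the pair
#'   (`n_pairs/2` each); otherwise all within-cluster samples come from the
#'   first cluster.
#' @return A `distance_samples` list with one record per retained cluster
#'   pair: `pair`, `intra`, `inter`.
#' @export
sample_cluster_distances <- function(D, labels, n_pairs = 1000L, seed = 1L,
                                     pool = TRUE) {
  D <- unclass(D)
  m <- length(labels)
  if (!all(dim(D) == m))
    stop("`D` must be m x m with m = length(labels)", call. = FALSE)
  labs <- factor(labels)
  lev <- levels(labs)
  if (length(lev) < 2L)
    stop("need at least 2 clusters", call. = FALSE)

  draw_within <- function(members, k) {
    i <- sample(members, k, replace = TRUE)
    j <- sample(members, k, replace = TRUE)
    # Redraw collisions so pairs are of distinct elements.
    while (any(bad <- i == j)) j[bad] <- sample(members, sum(bad),
                                                replace = TRUE)
    D[cbind(i, j)]
  }

  with_seed(seed, {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
    out <- list()
    for (pr in pairs) {
      mem_a <- which(labs == pr[1])
      mem_b <- which(labs == pr[2])
      if (length(mem_a) < 2L || length(mem_b) < 2L) {
        warning(sprintf("cluster pair (%s, %s) skipped: singleton cluster",
                        pr[1], pr[2]), call. = FALSE)
        next
      }
      if (pool) {
        k_a <- n_pairs %/% 2L
        intra <- c(draw_within(mem_a, k_a), draw_within(mem_b, n_pairs - k_a))
      } else {
        intra <- draw_within(mem_a, n_pairs)
      }
      ii <- sample(mem_a, n_pairs, replace = TRUE)
      jj <- sample(mem_b, n_pairs, replace = TRUE)
      inter <- D[cbind(ii, jj)]
      out[[length(out) + 1L]] <- list(pair = pr, intra = intra, inter = inter)
    }
    structure(out, class = "distance_samples")
  })
}

#' One-tailed tests of intra- vs inter-cluster distances
#'
#' Welch one-tailed t-test of H1: mean(intra) < mean(inter) for every cluster
#' pair, with Benjamini-Hochberg FDR adjustment across pairs.  Two identical
#' zero-variance distributions get p = 0.5 by convention.
#'
#' @param samples A [sample_cluster_distances()] result.
#' @param alpha Significance threshold used for the `significant` flag.
#' @return Data frame: cluster_a, cluster_b, intra_mean, intra_sd,
#'   inter_mean, inter_sd, t, p, p_adj, significant.
#' @export
intra_inter_test <- function(samples, alpha = 0.05) {
  if (length(samples) == 0L)
    stop("no cluster pairs to test", call. = FALSE)
  rows <- lapply(samples, function(sm) {
    if (var(sm$intra) == 0 && var(sm$inter) == 0 &&
        mean(sm$intra) == mean(sm$inter)) {
      tt <- list(statistic = 0, p.value = 0.5)
    } else if (var(sm$intra) == 0 && var(sm$inter) == 0) {
      tt <- list(statistic = if (mean(sm$intra) < mean(sm$inter)) -Inf else Inf,
                 p.value = if (mean(sm$intra) < mean(sm$inter)) 0 else 1)
    } else {
      ht <- t.test(sm$intra, sm$inter, alternative = "less",
                   var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(cluster_a = sm$pair[1], cluster_b = sm$pair[2],
               intra_mean = mean(sm$intra), intra_sd = sd(sm$intra),
               inter_mean = mean(sm$inter), inter_sd = sd(sm$inter),
               t = tt$statistic, p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Validate a clustering by Riemannian distance separation
#'
#' Convenience wrapper: sample distances for every cluster pair and run the
#' one-tailed tests with FDR correction.
#'
#' @inheritParams sample_cluster_distances
#' @inheritParams intra_inter_test
#' @return The [intra_inter_test()] table.
#' @export
validate_clusters <- function(D, labels, n_pairs = 1000L, seed = 1L,
                              alpha = 0.05, pool = TRUE) {
  samples <- sample_cluster_distances(D, labels, n_pairs = n_pairs,
                                      seed = seed, pool = pool)
  intra_inter_test(samples, alpha = alpha)
}
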
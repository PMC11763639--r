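# Clustering evaluation metrics and the cross-algorithm statistical
# comparison protocol.

# Two labelings describe the same partition iff every cluster maps onto
# exactly one class and vice versa.
same_partition <- function(labels, truth) {
  tab <- table(labels, truth)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

pair_confusion <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("`labels` and `truth` must have equal length", call. = FALSE)
  tab <- table(labels, truth)
  n <- length(labels)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  tp <- sum_ij
  fp <- sum_a - sum_ij
  fn <- sum_b - sum_ij
  tn <- total - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn, total = total,
       sum_a = sum_a, sum_b = sum_b)
}

#' Adjusted Rand Index
#'
#' Pair-counting agreement between two partitions, adjusted for chance so
#' that random labelings score around zero and identical partitions score 1.
#'
#' @param labels,truth Equal-length label vectors (any atomic type).
#' @return A scalar in `[-1, 1]`.
#' @export
ari <- function(labels, truth) {
  pc <- pair_confusion(labels, truth)
  expected <- pc$sum_a * pc$sum_b / pc$total
  max_index <- (pc$sum_a + pc$sum_b) / 2
  if (max_index == expected) {
    # Both partitions trivial (single cluster or all singletons).
    return(if (same_partition(labels, truth)) 1 else 0)
  }
  (pc$tp - expected) / (max_index - expected)
}

partition_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p))
}

#' Normalized Mutual Information
#'
#' Mutual information between the two partitions normalized by the geometric
#' mean of their entropies (natural logarithms; the normalization cancels the
#' base).  When either partition has zero entropy the value is defined as 1
#' if the partitions are identical and 0 otherwise.
#'
#' @inheritParams ari
#' @return A scalar in `[0, 1]`.
#' @export
nmi <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("`labels` and `truth` must have equal length", call. = FALSE)
  hu <- partition_entropy(labels)
  hv <- partition_entropy(truth)
  if (hu == 0 || hv == 0)
    return(if (same_partition(labels, truth)) 1 else 0)
  tab <- table(labels, truth)
  n <- length(labels)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  keep <- pij > 0
  mi <- sum(pij[keep] * log(pij[keep] / outer(pi_, p_j)[keep]))
  mi / sqrt(hu * hv)
}

#' Purity score
#'
#' Fraction of points lying in the majority true class of their cluster:
#' `(1/T) sum_k max_j |cluster_k intersect class_j|`.
#'
#' @inheritParams ari
#' @return A scalar in `[0, 1]`.
#' @export
purity <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("`labels` and `truth` must have equal length", call. = FALSE)
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / length(labels)
}

#' Pair-counting F1 score
#'
#' Precision and recall over same-cluster pairs (TP = pairs together in both
#' partitions, FP = together only in `labels`, FN = together only in
#' `truth`); F1 is their harmonic mean.  Defined as 0 when no positive pairs
#' are predicted.
#'
#' @inheritParams ari
#' @return A scalar in `[0, 1]`.
#' @export
pair_f1 <- function(labels, truth) {
  pc <- pair_confusion(labels, truth)
  if (pc$tp + pc$fp == 0 && pc$fn == 0) {
    # No positive pairs on either side (both partitions all singletons):
    # identical partitions by convention.
    return(1)
  }
  if (pc$tp + pc$fp == 0 || pc$tp + pc$fn == 0 || pc$tp == 0) return(0)
  p <- pc$tp / (pc$tp + pc$fp)
  r <- pc$tp / (pc$tp + pc$fn)
  2 * p * r / (p + r)
}

#' Silhouette score from a precomputed distance matrix
#'
#' Mean over points of `(b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' distance to the point's own cluster and `b_i` the mean distance to the
#' nearest other cluster.  Intended for the pairwise Riemannian distance
#' matrix between segment SCMs; singleton clusters contribute 0.
#'
#' @param labels Cluster labels (length m).
#' @param D m x m symmetric distance matrix.
#' @return A scalar in `[-1, 1]`.
#' @export
riemannian_silhouette <- function(labels, D) {
  D <- unclass(D)
  m <- length(labels)
  if (!all(dim(D) == m))
    stop("`D` must be m x m with m = length(labels)", call. = FALSE)
  labs <- as.integer(factor(labels))
  k <- max(labs)
  if (k < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  sizes <- tabulate(labs, k)
  # Mean distance from every point to every cluster.
  member <- outer(labs, seq_len(k), "==") * 1
  sums <- D %*% member
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- labs[i]
    if (sizes[own] == 1L) {
      s[i] <- 0
      next
    }
    a <- sums[i, own] / (sizes[own] - 1L)
    b <- min(sums[i, -own] / sizes[-own])
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Compare algorithms' per-dataset scores against a reference
#'
#' For one metric, takes a datasets x algorithms score matrix and compares
#' every other algorithm with the reference column using paired tests:
#' Shapiro-Wilk decides between paired t-tests (all columns normal at
#' `alpha`) and paired Wilcoxon signed-rank tests, and Benjamini-Hochberg FDR
#' adjusts across the comparisons.  Zero-difference pairs are dropped before
#' the Wilcoxon test (identical vectors give p = 1).
#'
#' @param scores Numeric matrix, rows = datasets, columns = algorithms (named).
#' @param ref Name or index of the reference column.
#' @param alpha Significance level for the normality gate.
#' @param method `"auto"` (Shapiro-Wilk gate), `"t"`, or `"wilcoxon"`.
#' @return Data frame: algorithm, shapiro_p, test, statistic, p, p_adj.
#' @export
compare_algorithms <- function(scores, ref, alpha = 0.05,
                               method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("alg", seq_len(ncol(scores)))
  if (is.character(ref)) ref <- match(ref, colnames(scores))
  if (is.na(ref) || ref < 1 || ref > ncol(scores))
    stop("`ref` must name a column of `scores`", call. = FALSE)

  shapiro_p <- apply(scores, 2L, function(x) {
    if (length(unique(x)) < 3L) return(0) # degenerate: not normal
    shapiro.test(x)$p.value
  })
  if (method == "auto")
    method <- if (all(shapiro_p > alpha)) "t" else "wilcoxon"

  others <- setdiff(seq_len(ncol(scores)), ref)
  res <- lapply(others, function(j) {
    d <- scores[, ref] - scores[, j]
    if (all(d == 0)) {
      return(data.frame(algorithm = colnames(scores)[j],
                        shapiro_p = shapiro_p[j], test = method,
                        statistic = NA_real_, p = 1))
    }
    if (method == "t" && var(d) == 0) {
      # A perfectly constant nonzero difference: the paired t statistic
      # diverges; report the limiting p-value.
      return(data.frame(algorithm = colnames(scores)[j],
                        shapiro_p = shapiro_p[j], test = method,
                        statistic = sign(mean(d)) * Inf, p = 0))
    }
    if (method == "t") {
      ht <- t.test(scores[, ref], scores[, j], paired = TRUE)
    } else {
      dd <- d[d != 0]
      ht <- suppressWarnings(
        wilcox.test(dd, alternative = "two.sided", exact = FALSE,
                    correct = TRUE))
    }
    data.frame(algorithm = colnames(scores)[j], shapiro_p = shapiro_p[j],
               test = method, statistic = unname(ht$statistic),
               p = ht$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
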
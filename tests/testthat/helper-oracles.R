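# Brute-force pair-counting oracles, independent of the contingency-table
# implementations under test.

brute_pairs <- function(labels, truth) {
  n <- length(labels)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_l <- labels[i] == labels[j]
    same_t <- truth[i] == truth[j]
    if (same_l && same_t) tp <- tp + 1
    else if (same_l && !same_t) fp <- fp + 1
    else if (!same_l && same_t) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Two labelings are the same partition iff no pair is split differently.
brute_same_partition <- function(labels, truth) {
  pc <- brute_pairs(labels, truth)
  pc$fp == 0 && pc$fn == 0
}

brute_ari <- function(labels, truth) {
  pc <- brute_pairs(labels, truth)
  n_pairs <- with(pc, tp + fp + fn + tn)
  sum_a <- pc$tp + pc$fp
  sum_b <- pc$tp + pc$fn
  expected <- sum_a * sum_b / n_pairs
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    # Both partitions trivial: 1 iff identical (the implementation's stated
    # convention for the degenerate case).
    return(if (brute_same_partition(labels, truth)) 1 else 0)
  }
  (pc$tp - expected) / (maxi - expected)
}

brute_f1 <- function(labels, truth) {
  pc <- brute_pairs(labels, truth)
  if (pc$tp + pc$fp == 0 && pc$fn == 0) return(1) # both all singletons
  if (pc$tp == 0) return(0)
  p <- pc$tp / (pc$tp + pc$fp)
  r <- pc$tp / (pc$tp + pc$fn)
  2 * p * r / (p + r)
}
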
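#' Multichannel EEG record
#'
#' Minimal container for a channels x samples matrix with its sampling rate.
#' Values must be finite; at least two channels are required (spatial
#' covariance needs a spatial dimension).
#'
#' @param data Numeric matrix, channels x samples.
#' @param srate_hz Sampling rate in Hz.
#' @param channel_names Optional character vector of channel names.
#' @return An `eeg_record` list.
#' @export
eeg_record <- function(data, srate_hz, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (nrow(data) < 2L)
    stop("at least 2 channels are required", call. = FALSE)
  stopifnot_scalar(srate_hz, "srate_hz")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must match the number of channels",
         call. = FALSE)
  structure(list(data = data, srate_hz = srate_hz,
                 channel_names = channel_names),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("eeg_record: %d channels x %d samples at %g Hz\n",
              nrow(x$data), ncol(x$data), x$srate_hz))
  invisible(x)
}

#' Sliding-window segmentation
#'
#' Cuts the record into overlapping windows of `t` samples advanced by `s`
#' samples and removes each window's per-channel mean.  Windows are 0-based
#' half-open `[start, start + t)`; a final partial window is discarded, so the
#' number of segments is `floor((T - t) / s) + 1`.
#'
#' @param record An [eeg_record()].
#' @param t Window length in samples.
#' @param s Step between window starts in samples.
#' @return A `segment_set`: `segments` (channels x t x m array of zero-meaned
#'   windows), `starts` (0-based), `t`, `s`, `srate_hz`.
#' @export
segment <- function(record, t, s = 1L) {
  if (!inherits(record, "eeg_record"))
    record <- eeg_record(record$data, record$srate_hz, record$channel_names)
  t <- as.integer(t)
  s <- as.integer(s)
  T_total <- ncol(record$data)
  if (t < 1L || t > T_total)
    stop(sprintf("window length t=%d must be in [1, %d]", t, T_total),
         call. = FALSE)
  if (s < 1L) stop("step s must be >= 1", call. = FALSE)

  starts <- seq.int(0L, T_total - t, by = s)
  m <- length(starts)
  n <- nrow(record$data)
  segs <- array(0, dim = c(n, t, m))
  for (i in seq_len(m)) {
    w <- record$data[, (starts[i] + 1L):(starts[i] + t), drop = FALSE]
    segs[, , i] <- w - rowMeans(w)
  }
  structure(list(segments = segs, starts = starts, t = t, s = s,
                 srate_hz = record$srate_hz,
                 channel_names = record$channel_names),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments of %d channels x %d samples (step %d)\n",
              dim(x$segments)[3], dim(x$segments)[1], x$t, x$s))
  invisible(x)
}

#' Spatial covariance matrix of one zero-meaned segment
#'
#' `C = X X' / (t - 1)`, optionally shrunk toward the scaled identity:
#' `C <- (1 - gamma) C + gamma * (tr(C)/n) I`.  Shrinkage preserves the trace
#' and guarantees positive definiteness when the raw SCM is rank deficient
#' (which happens whenever `t - 1 < n`).
#'
#' @param segment Numeric matrix, channels x samples, zero-meaned per channel.
#' @param gamma Shrinkage weight in `[0, 1]`.
#' @return A symmetric positive definite channels x channels matrix.
#' @export
compute_scm <- function(segment, gamma = 0) {
  if (!is.matrix(segment) || ncol(segment) < 2L)
    stop("`segment` must be a matrix with at least 2 samples", call. = FALSE)
  if (gamma < 0 || gamma > 1)
    stop("`gamma` must be in [0, 1]", call. = FALSE)
  n <- nrow(segment)
  t <- ncol(segment)
  C <- tcrossprod(segment) / (t - 1)
  if (gamma > 0)
    C <- (1 - gamma) * C + gamma * (sum(diag(C)) / n) * diag(n)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(paste0("segment SCM is singular (all-zero segment or t - 1 < n); ",
                "use shrinkage gamma > 0"), call. = FALSE)
  (C + t(C)) / 2
}

#' Spatial covariance matrices of every segment
#'
#' @param segments A [segment()] result.
#' @param gamma Shrinkage weight.  The default (`NULL`) uses 0.05 when the
#'   raw SCMs are rank deficient — either structurally (`t - 1 < n`) or
#'   numerically (smallest eigenvalue below `1e-10` of the mean per-channel
#'   variance, as happens when fewer sources than channels are active in a
#'   window) — and 0 otherwise.
#' @return An `scm_set`: `matrices` (n x n x m array), `gamma`, plus the
#'   segment metadata (`starts`, `t`, `s`, `srate_hz`).
#' @export
scm_set <- function(segments, gamma = NULL) {
  if (!inherits(segments, "segment_set"))
    stop("`segments` must be a segment_set", call. = FALSE)
  d <- dim(segments$segments)
  n <- d[1]
  t <- d[2]
  m <- d[3]
  if (is.null(gamma)) {
    if (t - 1 < n) {
      gamma <- 0.05
    } else {
      rel_min <- vapply(seq_len(m), function(i) {
        X <- segments$segments[, , i]
        C <- tcrossprod(X) / (t - 1)
        ev <- eigen((C + t(C)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values
        min(ev) / (sum(diag(C)) / n)
      }, numeric(1))
      gamma <- if (min(rel_min) < 1e-10) 0.05 else 0
    }
  }
  mats <- array(0, dim = c(n, n, m))
  for (i in seq_len(m))
    mats[, , i] <- compute_scm(segments$segments[, , i], gamma = gamma)
  structure(list(matrices = mats, gamma = gamma, starts = segments$starts,
                 t = segments$t, s = segments$s, srate_hz = segments$srate_hz),
            class = "scm_set")
}

#' @export
print.scm_set <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("scm_set: %d SPD matrices of size %dx%d (shrinkage gamma=%g)\n",
              d[3], d[1], d[2], x$gamma))
  invisible(x)
}

#' Ground-truth label of each segment
#'
#' Maps per-sample labels to segments by taking the label at each window's
#' center sample (`start + floor(t/2)`).
#'
#' @param truth Per-sample integer labels.
#' @param starts 0-based window starts.
#' @param t Window length in samples.
#' @return Integer vector, one label per segment.
#' @export
segment_truth <- function(truth, starts, t) {
  centers <- starts + t %/% 2L
  if (max(centers) + 1L > length(truth))
    stop("window centers exceed the label vector", call. = FALSE)
  truth[centers + 1L]
}
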
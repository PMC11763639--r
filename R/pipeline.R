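# End-to-end orchestration: segment -> SCMs -> distance matrices -> fused
# features -> deep embedded clustering -> microstate sequence and
# representatives.

#' Run configuration for the full pipeline
#'
#' @param window_ms Sliding-window length in milliseconds (used when
#'   `window_samples` is `NULL`).
#' @param window_samples Window length in samples (overrides `window_ms`).
#' @param step_samples Step between windows in samples.
#' @param n_clusters Number of microstate clusters s (>= 2).
#' @param gamma SCM shrinkage; `NULL` = automatic (0.05 when the window is
#'   rank deficient, else 0).
#' @param encoder An [encoder_spec()]; its `seed` controls all pipeline
#'   randomness.
#' @param interval Optional analysis interval `c(start_ms, end_ms)`
#'   (half-open) cut from the record before segmentation; `NULL` = full
#'   record.
#' @return A `run_config` list.
#' @export
run_config <- function(window_ms = 200, window_samples = NULL,
                       step_samples = 1L, n_clusters = 5L, gamma = NULL,
                       encoder = encoder_spec(), interval = NULL) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  structure(list(window_ms = window_ms, window_samples = window_samples,
                 step_samples = as.integer(step_samples),
                 n_clusters = as.integer(n_clusters), gamma = gamma,
                 encoder = encoder, interval = interval),
            class = "run_config")
}

#' Cluster a recording into microstates
#'
#' Executes the full pipeline on one channels x samples recording: sliding
#' windows, spatial covariance matrices, sensor- and source-space distance
#' matrices, MDS feature fusion, deep embedded clustering, microstate
#' sequence assembly, and per-cluster representative segments.  Fully
#' reproducible from the record, the configuration, and the encoder seed.
#'
#' @param record An [eeg_record()].
#' @param config A [run_config()].
#' @return A `spade_result` list: `model` ([dec_fit()] output), `sequence`
#'   ([labels_to_sequence()] output), `covset`, `distances` (list of sensor
#'   and source matrices), `features`, `segment_labels`,
#'   `representatives` (per-cluster segment index or NA for empty clusters),
#'   and the echoed `config`.
#' @export
run_spade <- function(record, config = run_config()) {
  if (!inherits(record, "eeg_record"))
    stop("`record` must be an eeg_record", call. = FALSE)
  offset <- 0L
  if (!is.null(config$interval)) {
    a <- round(config$interval[1] * record$srate_hz / 1000)
    b <- round(config$interval[2] * record$srate_hz / 1000)
    record <- eeg_record(record$data[, (a + 1L):b, drop = FALSE],
                         record$srate_hz, record$channel_names)
    offset <- a
  }
  t_samp <- if (!is.null(config$window_samples)) config$window_samples else
    as.integer(round(config$window_ms * record$srate_hz / 1000))

  segs <- segment(record, t = t_samp, s = config$step_samples)
  covset <- scm_set(segs, gamma = config$gamma)
  dists <- pairwise_distances_both(covset)
  V <- build_features(covset, dists$sensor, dists$source)

  spec <- config$encoder
  spec$input_dim <- ncol(V)
  model <- dec_fit(V, spec, s = config$n_clusters)

  seq_out <- labels_to_sequence(model$labels, segs$starts, segs$t,
                                ncol(record$data), srate_hz = record$srate_hz,
                                offset_samples = offset)
  reps <- vapply(seq_len(config$n_clusters), function(k) {
    if (!any(model$labels == k)) return(NA_integer_)
    representative_segment(covset, model$labels, k, D = dists$source)
  }, integer(1))

  structure(list(model = model, sequence = seq_out, covset = covset,
                 distances = dists, features = V,
                 segment_labels = model$labels, representatives = reps,
                 config = config),
            class = "spade_result")
}

#' @export
print.spade_result <- function(x, ...) {
  cat(sprintf("spade_result: %d segments -> %d clusters, %d microstate runs\n",
              length(x$segment_labels), nrow(x$model$U),
              nrow(x$sequence$runs)))
  invisible(x)
}

#' Expand segment labels to a per-sample microstate sequence
#'
#' Every sample takes the label of the segment whose center is nearest
#' (ties to the earlier segment); samples before the first or after the last
#' center take the flanking segment's label.  Runs of constant label form
#' the microstate sequence.
#'
#' @param segment_labels Per-segment cluster labels.
#' @param starts 0-based segment start indices.
#' @param t Window length in samples.
#' @param T_total Number of samples to label.
#' @param srate_hz Sampling rate used to express runs in milliseconds.
#' @param offset_samples Sample offset of the analysis interval within the
#'   original recording (shifts the run times).
#' @return A `microstate_sequence` list: `labels` (length `T_total`) and
#'   `runs` (data frame: state, start_ms, end_ms, half-open).
#' @export
labels_to_sequence <- function(segment_labels, starts, t, T_total,
                               srate_hz = 1000, offset_samples = 0L) {
  if (length(segment_labels) != length(starts))
    stop("`segment_labels` must align with `starts`", call. = FALSE)
  centers <- starts + t %/% 2L # 0-based
  # Boundaries between consecutive centers; exact midpoints (possible only
  # for even center gaps) go to the earlier segment.
  p <- 0:(T_total - 1L)
  idx <- findInterval(p, centers + 0.5) # 0 before first center
  idx[idx == 0L] <- 1L
  # findInterval gives the last center <= p; nearest-center needs comparing
  # with the next center.
  nxt <- pmin(idx + 1L, length(centers))
  d_cur <- abs(p - centers[idx])
  d_nxt <- abs(centers[nxt] - p)
  use_next <- d_nxt < d_cur
  idx[use_next] <- nxt[use_next]
  labels <- segment_labels[idx]

  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts_run <- ends - r$lengths
  runs <- data.frame(
    state = r$values,
    start_ms = (starts_run + offset_samples) * 1000 / srate_hz,
    end_ms = (ends + offset_samples) * 1000 / srate_hz)
  structure(list(labels = labels, runs = runs,
                 srate_hz = srate_hz, offset_samples = offset_samples),
            class = "microstate_sequence")
}

#' @export
print.microstate_sequence <- function(x, ...) {
  cat(sprintf("microstate_sequence: %d samples, %d runs\n",
              length(x$labels), nrow(x$runs)))
  print(x$runs)
  invisible(x)
}

#' Representative segment of a cluster
#'
#' The member whose SCM minimizes the sum of squared Riemannian distances to
#' the other members — the member closest to the cluster's Fréchet mean.
#' Ties go to the smallest index.
#'
#' @param covset An [scm_set()].
#' @param labels Per-segment cluster labels.
#' @param cluster_id The cluster to summarize.
#' @param D Optional precomputed source-space distance matrix (computed
#'   from the member SCMs if missing).
#' @return The representative segment's index (into the full segment set).
#' @export
representative_segment <- function(covset, labels, cluster_id, D = NULL) {
  members <- which(labels == cluster_id)
  if (length(members) == 0L)
    stop(sprintf("cluster %s is empty", cluster_id), call. = FALSE)
  if (length(members) == 1L) return(members)
  if (is.null(D)) {
    sub <- covset$matrices[, , members, drop = FALSE]
    D_sub <- unclass(pairwise_distances(sub, kind = "source"))
  } else {
    D_sub <- unclass(D)[members, members, drop = FALSE]
  }
  cost <- rowSums(D_sub^2)
  members[which.min(cost)] # which.min ties to the first (smallest index)
}
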
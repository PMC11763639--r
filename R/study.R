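# The simulation comparison study: generate simulated datasets, run the
# requested clustering algorithms on each, and score them with the five
# evaluation metrics.

#' Run the simulation comparison study
#'
#' Generates `n_datasets` trial-averaged simulated recordings (a fresh random
#' mixing matrix and fresh trial randomness per dataset), runs the requested
#' algorithms with `s` clusters on each, and scores every result with ARI,
#' NMI, purity, pair-F1 and the Riemannian-distance silhouette.
#'
#' Alignment: per-segment algorithms (`spade`, `scm_kmeans`, `ae_kmeans`,
#' `tangent`, `softdtw`) are scored on their segment labels against the
#' ground-truth state at each window's center sample; per-sample algorithms
#' (`gfp`, `gmm`) on all samples against the per-sample truth.  Silhouette
#' always uses a pairwise Riemannian SCM distance matrix: the 200 ms-window
#' matrix shared by the SCM-based algorithms (per-sample labels are mapped
#' onto that grid at window centers), except soft-DTW which is scored on the
#' SCMs of its own 100 ms segmentation.
#'
#' @param n_datasets Number of simulated datasets.
#' @param algorithms Character subset of `"spade"`, `"gfp"`, `"gmm"`,
#'   `"softdtw"`, `"scm_kmeans"`, `"ae_kmeans"`, `"tangent"`.
#' @param s Number of clusters.
#' @param seed Master seed; every dataset and algorithm derives its own
#'   stream from it.
#' @param window_ms Window length for the SCM-based algorithms and SPADE.
#' @param softdtw_window_ms Window length for the soft-DTW baseline.
#' @param softdtw_downsample Temporal decimation factor for the soft-DTW
#'   baseline's internal representation (see [softdtw_cluster()]).
#' @param config Template [simulation_config()]; its seeds are overridden
#'   per dataset.
#' @param verbose Print one line per dataset.
#' @return A `simulation_study` list: `scores` (named list of datasets x
#'   algorithms matrices, one per metric) and `per_sample_scores` (same
#'   metrics for the per-sample microstate sequences of every algorithm).
#' @export
simulation_study <- function(n_datasets = 30L,
                             algorithms = c("spade", "gfp", "gmm", "softdtw",
                                            "scm_kmeans", "ae_kmeans",
                                            "tangent"),
                             s = 5L, seed = 1L, window_ms = 200,
                             softdtw_window_ms = 100, softdtw_downsample = 2L,
                             config = simulation_config(),
                             verbose = FALSE) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  metrics <- c("ari", "nmi", "purity", "f1", "silhouette")
  scores <- lapply(metrics, function(mm)
    matrix(NA_real_, n_datasets, length(algorithms),
           dimnames = list(NULL, algorithms)))
  names(scores) <- metrics
  seq_scores <- scores

  for (d in seq_len(n_datasets)) {
    cfg <- config
    cfg$mixing_seed <- as.integer(child_seed(seed, 2L * d))
    cfg$trial_seed <- as.integer(child_seed(seed, 2L * d + 1L))
    sim <- simulate_eeg(cfg)
    record <- sim$record
    truth <- sim$truth
    alg_seed <- function(a) as.integer(child_seed(seed, 1000L * d + a))

    t_samp <- as.integer(round(window_ms * record$srate_hz / 1000))
    segs <- segment(record, t = t_samp, s = 1L)
    covset <- scm_set(segs)
    dists <- pairwise_distances_both(covset)
    seg_truth <- segment_truth(truth, segs$starts, segs$t)

    results <- list()
    for (a in seq_along(algorithms)) {
      alg <- algorithms[a]
      res <- switch(
        alg,
        spade = {
          spec <- encoder_spec(input_dim = 3L * nrow(record$data),
                               seed = alg_seed(a))
          V <- build_features(covset, dists$sensor, dists$source)
          model <- dec_fit(V, spec, s = s)
          list(labels = model$labels, granularity = "segment")
        },
        gfp = list(labels = gfp_microstates(record, s = s,
                                            seed = alg_seed(a))$labels,
                   granularity = "sample"),
        gmm = list(labels = gmm_cluster(record, s = s,
                                        seed = alg_seed(a))$labels,
                   granularity = "sample"),
        softdtw = {
          t_dtw <- as.integer(round(softdtw_window_ms * record$srate_hz /
                                      1000))
          segs_dtw <- segment(record, t = t_dtw, s = 1L)
          list(labels = softdtw_cluster(segs_dtw, s = s, seed = alg_seed(a),
                                        downsample = softdtw_downsample)$labels,
               granularity = "segment", segs = segs_dtw)
        },
        scm_kmeans = list(labels = scm_vector_kmeans(covset, s = s,
                                                     seed = alg_seed(a))$labels,
                          granularity = "segment"),
        ae_kmeans = {
          spec <- encoder_spec(seed = alg_seed(a))
          list(labels = ae_kmeans(covset, spec, s = s)$labels,
               granularity = "segment")
        },
        tangent = list(labels = tangent_kmeans(covset, s = s,
                                               seed = alg_seed(a))$labels,
                       granularity = "segment"))
      results[[alg]] <- res
    }

    for (a in seq_along(algorithms)) {
      alg <- algorithms[a]
      res <- results[[alg]]
      if (res$granularity == "segment" && alg == "softdtw") {
        segs_dtw <- res$segs
        cov_dtw <- scm_set(segs_dtw)
        D_dtw <- pairwise_distances(cov_dtw, kind = "source")
        tru <- segment_truth(truth, segs_dtw$starts, segs_dtw$t)
        sil <- safe_silhouette(res$labels, D_dtw)
        seq_labels <- labels_to_sequence(res$labels, segs_dtw$starts,
                                         segs_dtw$t, ncol(record$data),
                                         record$srate_hz)$labels
      } else if (res$granularity == "segment") {
        tru <- seg_truth
        sil <- safe_silhouette(res$labels, dists$source)
        seq_labels <- labels_to_sequence(res$labels, segs$starts, segs$t,
                                         ncol(record$data),
                                         record$srate_hz)$labels
      } else {
        tru <- truth
        grid_labels <- res$labels[segs$starts + segs$t %/% 2L + 1L]
        sil <- safe_silhouette(grid_labels, dists$source)
        seq_labels <- res$labels
      }
      labels <- res$labels
      scores$ari[d, a] <- ari(labels, tru)
      scores$nmi[d, a] <- nmi(labels, tru)
      scores$purity[d, a] <- purity(labels, tru)
      scores$f1[d, a] <- pair_f1(labels, tru)
      scores$silhouette[d, a] <- sil

      seq_scores$ari[d, a] <- ari(seq_labels, truth)
      seq_scores$nmi[d, a] <- nmi(seq_labels, truth)
      seq_scores$purity[d, a] <- purity(seq_labels, truth)
      seq_scores$f1[d, a] <- pair_f1(seq_labels, truth)
      seq_scores$silhouette[d, a] <- sil
    }
    if (verbose)
      message(sprintf("dataset %d/%d done (ARI: %s)", d, n_datasets,
                      paste(sprintf("%s=%.3f", algorithms, scores$ari[d, ]),
                            collapse = " ")))
  }
  structure(list(scores = scores, per_sample_scores = seq_scores,
                 algorithms = algorithms, n_datasets = n_datasets,
                 s = s, seed = seed),
            class = "simulation_study")
}

safe_silhouette <- function(labels, D) {
  tryCatch(riemannian_silhouette(labels, D), error = function(e) NA_real_)
}

#' Mean score table of a simulation study
#'
#' @param study A [simulation_study()] result.
#' @param alignment `"native"` (the study's primary alignment) or
#'   `"per_sample"` (every algorithm's expanded microstate sequence).
#' @return Data frame: algorithm x metric means.
#' @export
study_means <- function(study, alignment = c("native", "per_sample")) {
  alignment <- match.arg(alignment)
  sc <- if (alignment == "native") study$scores else study$per_sample_scores
  out <- data.frame(algorithm = study$algorithms)
  for (mm in names(sc)) out[[mm]] <- colMeans(sc[[mm]])
  out
}
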
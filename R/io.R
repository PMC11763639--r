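# Plain-text readers and writers for records, labels, distance matrices and
# run tables.

#' Read a channels x samples EEG matrix from delimited text
#'
#' Expects tab- or comma-separated text with one row per channel; an optional
#' first column of channel names is detected automatically.
#'
#' @param path File path.
#' @param srate_hz Sampling rate of the recording.
#' @param sep Field separator (`"\t"` or `","`; guessed from the extension
#'   when `NULL`).
#' @return An [eeg_record()].
#' @export
read_eeg_record <- function(path, srate_hz, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE)
  names_col <- !is.numeric(raw[[1L]]) && all(is.na(suppressWarnings(
    as.numeric(raw[[1L]]))))
  if (names_col) {
    channel_names <- as.character(raw[[1L]])
    mat <- as.matrix(raw[, -1L, drop = FALSE])
  } else {
    channel_names <- NULL
    mat <- as.matrix(raw)
  }
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  eeg_record(mat, srate_hz = srate_hz, channel_names = channel_names)
}

#' Write per-sample or per-segment labels, one integer per line
#'
#' @param labels Integer labels.
#' @param path Output file.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Write a distance matrix as delimited text with a descriptive header
#'
#' The first line is a comment naming the kind and symmetrization; the rest
#' is the dense tab-separated matrix.
#'
#' @param D A [pairwise_distances()] matrix.
#' @param path Output file.
#' @export
write_distance_matrix <- function(D, path) {
  kind <- attr(D, "kind")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s symmetrized=%s",
                     if (is.null(kind)) "unknown" else kind,
                     isTRUE(attr(D, "symmetrized"))), con)
  write.table(unclass(D), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a microstate run table
#'
#' @param sequence A [labels_to_sequence()] result.
#' @param path Output file (tab-separated: state, start_ms, end_ms).
#' @export
write_runs <- function(sequence, path) {
  write.table(sequence$runs, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `data.tsv` (channels x samples with a channel-name column),
#' `truth.txt` (one ground-truth state per line) and `config.json` (the
#' echoed configuration).
#'
#' @param sim A [simulate_eeg()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulated_eeg <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(channel = sim$record$channel_names, sim$record$data)
  write.table(df, file.path(dir, "data.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write_labels(sim$truth, file.path(dir, "truth.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- unclass(sim$config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
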
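#' Write a labeled amplitude dataset to a plain-text container
#'
#' Serializes a `cv_dataset` to a directory: `meta.json` (sampling rate,
#' window, bands, dimensions), `labels.csv` (trial labels and event index),
#' and one long-format `amplitude_<band>.csv` per band (columns trial,
#' electrode, sample, value). Everything is plain text, so containers can
#' be versioned and inspected directly.
#'
#' @param dataset A `cv_dataset` (see [simulate_amplitude_dataset()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cv_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(dataset$amplitudes[[1]])
  meta <- list(fs = dataset$fs, window_pre_s = dataset$window[1],
               window_post_s = dataset$window[2],
               event_index = dataset$event_index,
               bands = names(dataset$amplitudes),
               n_trials = dims[1], n_electrodes = dims[2], n_time = dims[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  utils::write.csv(data.frame(trial = seq_along(dataset$labels),
                              label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  for (b in names(dataset$amplitudes)) {
    arr <- dataset$amplitudes[[b]]
    long <- data.frame(
      trial = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
      electrode = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
      sample = rep(seq_len(dims[3]), each = dims[1] * dims[2]),
      value = as.vector(arr)
    )
    utils::write.csv(long, file.path(dir, paste0("amplitude_", b, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a plain-text amplitude container
#'
#' @param dir Directory written by [write_cv_dataset()].
#' @return A `cv_dataset` (without generator truth).
#' @export
read_cv_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(dir, "labels.csv"))$label
  amplitudes <- lapply(meta$bands, function(b) {
    long <- utils::read.csv(file.path(dir, paste0("amplitude_", b, ".csv")))
    arr <- array(0, dim = c(meta$n_trials, meta$n_electrodes, meta$n_time))
    arr[cbind(long$trial, long$electrode, long$sample)] <- long$value
    arr
  })
  names(amplitudes) <- meta$bands
  window <- c(meta$window_pre_s, meta$window_post_s)
  n_t <- meta$n_time
  structure(list(amplitudes = amplitudes, labels = labels,
                 t = (seq_len(n_t) - 1) / meta$fs - window[1],
                 fs = meta$fs, window = window,
                 event_index = meta$event_index, truth = NULL),
            class = "cv_dataset")
}

#' Export the articulatory feature table as CSV
#'
#' @param inventory A [make_inventory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(inventory, path) {
  df <- data.frame(cv = inventory$cvs, inventory$features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
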
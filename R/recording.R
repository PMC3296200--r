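#' Multichannel biosignal recording
#'
#' Container for a multichannel EEG/ECG recording: a channels-by-samples
#' numeric matrix with a sampling rate and channel labels. All amplitude
#' units are accepted; fractal-dimension estimates are invariant under
#' amplitude scaling, while the averaging filter operates on whatever
#' physical units the file carries.
#'
#' @param data numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param start_time offset of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `fs`, `labels`, `start_time`.
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), fs = 100)
#' rec
#' @export
recording <- function(data, fs, labels = NULL, start_time = 0) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop_data("recording data must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop_data("recording needs >= 1 channel and >= 2 samples")
  if (!all(is.finite(data)))
    stop_data("recording contains non-finite samples (NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_config("sampling rate fs must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop_data("number of labels must equal number of channels")
  if (anyDuplicated(labels))
    stop_data("channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
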
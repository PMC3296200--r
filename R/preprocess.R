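#' Moving-average (averaging) low-pass filter
#'
#' Replaces every sample by the mean of its `2k+1`-point neighbourhood
#' (`k` samples on each side). This is the crude low-pass stage used to
#' suppress very-high-frequency and white noise before blind source
#' separation; `k = 3` (a 7-point average) is the default working value.
#' At the series boundaries the window shrinks to the available neighbours,
#' so the output has the same length as the input and no edge padding
#' artefacts enter subsequent windowed analyses. `boundary = "reflect"`
#' instead mirror-pads the ends.
#'
#' @param x numeric series of length N.
#' @param k half-window length in samples, integer >= 0. `k = 0` returns
#'   `x` unchanged.
#' @param boundary `"shrink"` (default) or `"reflect"`.
#' @return Filtered series, same length as `x`.
#' @examples
#' moving_average(c(0, 3, 6, 9, 12), k = 1)  # 1.5 3 6 9 10.5
#' @export
moving_average <- function(x, k = 3, boundary = c("shrink", "reflect")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k))
    stop_param("k must be a single non-negative integer")
  k <- as.integer(k)
  n <- length(x)
  if (n < 2L * k + 1L)
    stop_param("series too short: need length >= 2k+1 = ", 2L * k + 1L)
  if (k == 0L) return(x)
  if (boundary == "reflect") {
    xp <- c(rev(x[2:(k + 1L)]), x, rev(x[(n - k):(n - 1L)]))
    cs <- cumsum(c(0, xp))
    return((cs[(2L * k + 2L):(n + 2L * k + 1L)] - cs[1:n]) / (2L * k + 1L))
  }
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Apply the averaging filter to every channel of a recording
#' @param rec an [recording()] object.
#' @inheritParams moving_average
#' @return A filtered [recording()].
#' @export
filter_recording <- function(rec, k = 3, boundary = "shrink") {
  out <- rec
  out$data <- t(apply(rec$data, 1, moving_average, k = k, boundary = boundary))
  rownames(out$data) <- rec$labels
  out
}

#' Remove the sample mean of each channel
#'
#' Centering makes the blind source separation model zero-mean; every row
#' of the result has sample mean numerically zero.
#'
#' @param X numeric matrix, channels as rows.
#' @return Matrix of the same shape with zero-mean rows.
#' @export
center_rows <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) < 2L) stop_param("need >= 2 samples per channel to center")
  X - rowMeans(X)
}
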
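#' Sliding analysis windows
#'
#' 0-based half-open sample ranges `[i*step, i*step + win_len)` with
#' `step = round(win_len * (1 - overlap))`. Trailing samples that do not
#' fill a complete window are dropped. The working configuration is
#' 2048-sample windows (16 s at 128 Hz) with 50% overlap, which resolves
#' seizure propagation without excessive estimator variance.
#'
#' @param n_samples series length.
#' @param win_len window length in samples (default 2048).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return data.frame with 0-based `start` and (exclusive) `end` columns.
#' @export
sliding_windows <- function(n_samples, win_len = 2048L, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop_param("overlap must be in [0, 1)")
  if (win_len < 2L) stop_param("win_len must be >= 2")
  if (n_samples < win_len)
    stop_param("series shorter than one window (", n_samples, " < ", win_len, ")")
  step <- max(1L, as.integer(round(win_len * (1 - overlap))))
  n_win <- floor((n_samples - win_len) / step) + 1L
  start <- (seq_len(n_win) - 1L) * step
  data.frame(start = start, end = start + win_len)
}

new_fd_timecourse <- function(times, fd, fd_sd, win_len, overlap, fs,
                              component_ids) {
  structure(
    list(times = times, fd = fd, fd_sd = fd_sd, win_len = win_len,
         overlap = overlap, fs = fs, component_ids = component_ids),
    class = "fd_timecourse"
  )
}

#' Sliding-window fractal-dimension time-course
#'
#' Computes the Higuchi fractal dimension of every component restricted to
#' every sliding window. Window timestamps are at window centres, in
#' seconds. A window on which the estimate is undefined (constant signal)
#' yields `NaN` with a warning rather than an error.
#'
#' @param components numeric matrix (`n_components x n_samples`) or vector.
#' @param fs sampling rate, Hz.
#' @param win_len,overlap window geometry, see [sliding_windows()].
#' @param k_max Higuchi regression range, see [higuchi_fd()].
#' @param start_time offset added to all timestamps, seconds.
#' @param component_ids labels for the rows (default `IC1, IC2, ...`).
#' @return Object of class `fd_timecourse`: `times` (window centres, s),
#'   `fd` and `fd_sd` matrices (`n_components x n_windows`), and the
#'   window geometry.
#' @export
fd_timecourse <- function(components, fs, win_len = 2048L, overlap = 0.5,
                          k_max = 64L, start_time = 0,
                          component_ids = NULL) {
  if (is.vector(components)) components <- matrix(components, nrow = 1)
  nc <- nrow(components)
  win <- sliding_windows(ncol(components), win_len, overlap)
  nw <- nrow(win)
  if (is.null(component_ids)) component_ids <- paste0("IC", seq_len(nc))
  fd <- matrix(NA_real_, nc, nw, dimnames = list(component_ids, NULL))
  fd_sd <- fd
  n_bad <- 0L
  for (w in seq_len(nw)) {
    cols <- (win$start[w] + 1L):win$end[w]
    for (ci in seq_len(nc)) {
      est <- tryCatch(higuchi_fd(components[ci, cols], k_max = k_max),
                      epifd_data_error = function(e) NULL)
      if (is.null(est)) {
        fd[ci, w] <- NaN; fd_sd[ci, w] <- NaN; n_bad <- n_bad + 1L
      } else {
        fd[ci, w] <- est$Df; fd_sd[ci, w] <- est$S_Df
      }
    }
  }
  if (n_bad > 0L)
    warning(n_bad, " window(s) had undefined fractal dimension (constant signal)")
  times <- start_time + (win$start + win_len / 2) / fs
  new_fd_timecourse(times, fd, fd_sd, as.integer(win_len), overlap, fs,
                    component_ids)
}

#' @export
print.fd_timecourse <- function(x, ...) {
  cat(sprintf("<fd_timecourse> %d component(s) x %d window(s), win %d samples, %.0f%% overlap\n",
              nrow(x$fd), ncol(x$fd), x$win_len, 100 * x$overlap))
  mfd <- rowMeans(x$fd, na.rm = TRUE)
  for (i in seq_along(mfd))
    cat(sprintf("  %-8s mean FD %.3f\n", x$component_ids[i], mfd[i]))
  invisible(x)
}

#' Select the main (epileptic) component
#'
#' Among the estimated components, the one carrying the seizure activity is
#' taken to be the one with the highest mean fractal dimension over all
#' windows (`NaN` windows excluded). Ties break deterministically to the
#' lowest component index.
#'
#' @param tc an `fd_timecourse`.
#' @return Integer component index, named by its component id.
#' @export
select_main_component <- function(tc) {
  m <- rowMeans(tc$fd, na.rm = TRUE)
  m[!is.finite(m)] <- -Inf
  if (all(m == -Inf)) stop_data("all components have all-NaN fractal dimensions")
  i <- which.max(m)              # which.max takes the first (lowest) index on ties
  stats::setNames(i, tc$component_ids[i])
}

#' Detect seizure onset from a fractal-dimension series
#'
#' Implements the FD-drop rule: preictally the fractal dimension sits on a
#' stable high plateau, declines as the seizure approaches, and reaches its
#' minimum at the ictal onset. The onset estimate is the time of the global
#' FD minimum after the baseline region. An earlier warning ("alarm") is
#' raised at the first run of `m_consec` consecutive windows falling below
#' `baseline_mean - alpha * baseline_sd`, restricted to runs starting at or
#' before the detected onset so the alarm never postdates it.
#'
#' @param fd numeric FD values per window (NaN allowed, excluded).
#' @param times window-centre times, seconds, same length.
#' @param baseline_n number of initial windows forming the baseline.
#' @param alpha drop threshold in baseline standard deviations.
#' @param m_consec consecutive sub-threshold windows required for an alarm.
#' @return Object of class `onset_detection`: `onset_index`, `onset_time_s`,
#'   `alarm_index`, `alarm_time_s` (NA if never), `baseline_mean`,
#'   `baseline_sd`, `degenerate` flag, `params`.
#' @export
detect_onset <- function(fd, times, baseline_n = 10L, alpha = 2.0,
                         m_consec = 3L) {
  nw <- length(fd)
  if (length(times) != nw) stop_param("fd and times lengths differ")
  if (nw < baseline_n + m_consec)
    stop_param("need at least baseline_n + m_consec = ", baseline_n + m_consec,
               " windows, got ", nw)
  base <- fd[seq_len(baseline_n)]
  if (all(!is.finite(base))) stop_data("baseline windows are all NaN")
  bmean <- mean(base, na.rm = TRUE)
  bsd <- stats::sd(base, na.rm = TRUE)
  if (!is.finite(bsd)) bsd <- 0
  post <- fd[(baseline_n + 1L):nw]
  finite_post <- post[is.finite(post)]
  degenerate <- length(finite_post) == 0L ||
    diff(range(finite_post)) < .Machine$double.eps * max(abs(finite_post), 1)
  onset_index <- if (length(finite_post) == 0L) baseline_n + 1L
                 else baseline_n + which.min(post)   # NA/NaN never the minimum
  thr <- bmean - alpha * bsd
  below <- is.finite(fd) & fd < thr
  alarm_index <- NA_integer_
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= m_consec & starts <= onset_index
  if (any(ok)) alarm_index <- starts[which(ok)[1]]
  structure(
    list(onset_index = onset_index,
         onset_time_s = times[onset_index],
         alarm_index = alarm_index,
         alarm_time_s = if (is.na(alarm_index)) NA_real_ else times[alarm_index],
         baseline_mean = bmean, baseline_sd = bsd, degenerate = degenerate,
         params = list(baseline_n = baseline_n, alpha = alpha,
                       m_consec = m_consec)),
    class = "onset_detection"
  )
}

#' @export
print.onset_detection <- function(x, ...) {
  cat(sprintf("<onset_detection> onset at %.1f s (window %d)%s\n",
              x$onset_time_s, x$onset_index,
              if (x$degenerate) " [degenerate: flat FD series]" else ""))
  if (is.na(x$alarm_index)) {
    cat("  no sustained-drop alarm\n")
  } else {
    cat(sprintf("  alarm at %.1f s (window %d), threshold %.3f\n",
                x$alarm_time_s, x$alarm_index,
                x$baseline_mean - x$params$alpha * x$baseline_sd))
  }
  invisible(x)
}

#' Fit the seizure-detection pipeline to a recording
#'
#' The main entry point. Two processing chains are available:
#' Method 1 is center -> whiten -> FastICA -> windowed Higuchi FD ->
#' main-component selection -> FD-drop onset detection; Method 2 applies the
#' moving-average filter to every channel first, then runs the same chain.
#' A single-channel recording (ECG mode) skips whitening and ICA and is
#' analysed directly (Method 2 still applies the averaging filter).
#'
#' @param rec an [recording()].
#' @param method 1 (ICA -> FD) or 2 (averaging filter -> ICA -> FD; default).
#' @param filter_k averaging-filter half-window, samples (Method 2 only).
#' @param nonlinearity,a1,tol,max_iter,var_keep FastICA settings, see
#'   [fastica()] and [whiten()].
#' @param win_len,overlap,k_max windowed FD settings.
#' @param baseline_n,alpha,m_consec onset-detector settings, see
#'   [detect_onset()].
#' @param seed RNG seed for the ICA initialization; fixing it makes the
#'   whole fit deterministic.
#' @return Object of class `seizure_fd`: the fd `timecourse`, the
#'   `detection` result on the selected `main_component`, the `ica` result
#'   (NULL in single-channel mode), and the full `config` echo.
#' @examples
#' sz <- gen_seizure_recording(duration_s = 96, onset_s = 60, fs = 128,
#'                             n_channels = 2, seed = 1, transition_s = 10,
#'                             plateau_s = 16, recovery_s = 10)
#' fit <- seizure_fd(sz$recording, method = 2, win_len = 1024, k_max = 32,
#'                   baseline_n = 3, seed = 1)
#' fit
#' @export
seizure_fd <- function(rec, method = 2L, filter_k = 3L,
                       nonlinearity = "g1", a1 = 1.0, tol = 1e-6,
                       max_iter = 200L, var_keep = 1.0,
                       win_len = 2048L, overlap = 0.5, k_max = 64L,
                       baseline_n = 10L, alpha = 2.0, m_consec = 3L,
                       seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!method %in% c(1L, 2L)) stop_config("method must be 1 or 2")
  config <- list(method = method, filter_k = filter_k,
                 nonlinearity = nonlinearity, a1 = a1, tol = tol,
                 max_iter = max_iter, var_keep = var_keep, win_len = win_len,
                 overlap = overlap, k_max = k_max, baseline_n = baseline_n,
                 alpha = alpha, m_consec = m_consec, seed = seed)
  X <- rec$data
  if (method == 2L) X <- t(apply(X, 1, moving_average, k = filter_k))
  ica <- NULL
  if (nrow(X) == 1L) {
    comps <- center_rows(X)
    ids <- rec$labels
  } else {
    Xc <- center_rows(X)
    wh <- whiten(Xc, var_keep = var_keep)
    ica <- fastica(wh$Xw, nl = ica_nonlinearity(nonlinearity, a1 = a1),
                   tol = tol, max_iter = max_iter, seed = seed,
                   whitening = wh)
    comps <- ica$S
    ids <- paste0("IC", seq_len(nrow(comps)))
  }
  tc <- fd_timecourse(comps, fs = rec$fs, win_len = win_len,
                      overlap = overlap, k_max = k_max,
                      start_time = rec$start_time, component_ids = ids)
  main <- select_main_component(tc)
  det <- detect_onset(tc$fd[main, ], tc$times, baseline_n = baseline_n,
                      alpha = alpha, m_consec = m_consec)
  structure(
    list(call = match.call(), method = method, config = config,
         timecourse = tc, ica = ica, main_component = main,
         detection = det, fs = rec$fs, n_channels = n_channels(rec)),
    class = "seizure_fd"
  )
}

#' @export
print.seizure_fd <- function(x, ...) {
  cat(sprintf("<seizure_fd> method %d, %d channel(s), %d component(s), %d window(s)\n",
              x$method, x$n_channels, nrow(x$timecourse$fd),
              ncol(x$timecourse$fd)))
  cat(sprintf("  main component: %s (mean FD %.3f)\n",
              names(x$main_component),
              mean(x$timecourse$fd[x$main_component, ], na.rm = TRUE)))
  print(x$detection)
  invisible(x)
}

#' @export
summary.seizure_fd <- function(object, ...) {
  print(object)
  cat("\nPer-component mean fractal dimension:\n")
  m <- rowMeans(object$timecourse$fd, na.rm = TRUE)
  for (i in seq_along(m))
    cat(sprintf("  %-8s %.4f%s\n", object$timecourse$component_ids[i], m[i],
                if (i == object$main_component) "  <- main" else ""))
  invisible(object)
}

#' @export
plot.seizure_fd <- function(x, ...) {
  tc <- x$timecourse
  graphics::matplot(tc$times, t(tc$fd), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "Higuchi FD",
                    main = sprintf("FD time-course (method %d)", x$method), ...)
  graphics::abline(v = x$detection$onset_time_s, col = "red3", lty = 2)
  if (!is.na(x$detection$alarm_time_s))
    graphics::abline(v = x$detection$alarm_time_s, col = "orange", lty = 3)
  graphics::legend("bottomleft", legend = tc$component_ids, lty = 1,
                   col = seq_len(nrow(tc$fd)), cex = 0.8)
  invisible(x)
}

#' Detection report as a plain list (JSON-ready)
#'
#' @param fit a [seizure_fd()] object.
#' @param timestamp include a wall-clock timestamp field (default TRUE).
#' @return Nested list mirroring the JSON report schema.
#' @export
as_report <- function(fit, timestamp = TRUE) {
  stopifnot(inherits(fit, "seizure_fd"))
  det <- fit$detection
  rep <- list(
    tool = "epifd",
    version = as.character(utils::packageVersion("epifd")),
    method = fit$method,
    config = fit$config,
    n_channels = fit$n_channels,
    n_components = nrow(fit$timecourse$fd),
    n_windows = ncol(fit$timecourse$fd),
    main_component = names(fit$main_component),
    main_component_index = as.integer(fit$main_component),
    onset_time_s = det$onset_time_s,
    alarm_time_s = if (is.na(det$alarm_time_s)) NULL else det$alarm_time_s,
    baseline_mean = det$baseline_mean,
    baseline_sd = det$baseline_sd,
    degenerate = det$degenerate
  )
  if (timestamp) rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  rep
}

#' Write the JSON detection report
#' @inheritParams as_report
#' @param path output path.
#' @param fd_csv optional path of the companion FD time-course CSV, recorded
#'   in the report.
#' @export
write_report <- function(fit, path, fd_csv = NULL, timestamp = TRUE) {
  rep <- as_report(fit, timestamp = timestamp)
  if (!is.null(fd_csv)) rep$fd_timecourse_file <- fd_csv
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
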
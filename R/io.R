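#' Read a multichannel recording from CSV or EDF
#'
#' The format is inferred from the file extension. CSV files hold one column
#' per channel; optional `#`-prefixed header lines may carry the sampling
#' rate (`# fs=128`) and channel labels (`# labels=Fp1,Fp2`), making a
#' single file self-describing. EDF (European Data Format) files are read
#' with physical (calibrated) sample values.
#'
#' @param path path to a `.csv` or `.edf` file.
#' @param fs_override sampling rate in Hz; required for CSV files without an
#'   `fs` header line, and overrides the file's value when given.
#' @return An [recording()] object, channels as rows, CSV column order
#'   preserved as channel order.
#' @export
read_recording <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    read_recording_csv(path, fs_override)
  } else if (ext == "edf") {
    rec <- read_edf(path)
    if (!is.null(fs_override)) rec$fs <- as.numeric(fs_override)
    rec
  } else {
    stop_config("unsupported recording format '.", ext, "' (expected .csv or .edf)")
  }
}

csv_header_fields <- function(path, n_probe = 50L) {
  head_lines <- readLines(path, n = n_probe, warn = FALSE)
  hdr <- grep("^\\s*#", head_lines, value = TRUE)
  out <- list()
  for (ln in hdr) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[key]] <- val
    }
  }
  out
}

read_recording_csv <- function(path, fs_override = NULL) {
  fields <- csv_header_fields(path)
  if (!is.null(fs_override)) fs_override <- suppressWarnings(as.numeric(fs_override))
  fs <- fs_override %||% (if (!is.null(fields$fs)) as.numeric(fields$fs))
  if (is.null(fs) || !is.finite(fs))
    stop_config("CSV recording needs a sampling rate: add '# fs=<Hz>' or pass fs_override")
  dat <- tryCatch(
    utils::read.table(path, sep = ",", header = FALSE, comment.char = "#",
                      colClasses = "numeric"),
    error = function(e) stop_data("cannot parse CSV recording: ", conditionMessage(e))
  )
  X <- t(as.matrix(dat))
  if (!all(is.finite(X))) stop_data("CSV recording contains NaN/Inf samples")
  labels <- if (!is.null(fields$labels)) {
    trimws(strsplit(fields$labels, ",", fixed = TRUE)[[1]])
  } else NULL
  start_time <- if (!is.null(fields$start_time)) as.numeric(fields$start_time) else 0
  recording(X, fs = fs, labels = labels, start_time = start_time)
}

#' Write a recording to CSV (or EDF)
#'
#' CSV output uses one column per channel with `#` header lines recording
#' the sampling rate and labels, so the file round-trips through
#' [read_recording()] without external metadata. `.edf` paths dispatch to
#' [write_edf()].
#'
#' @param rec an [recording()] object.
#' @param path output path; format chosen by extension.
#' @param digits significant digits for CSV samples (default 17: exact
#'   double round-trip).
#' @export
write_recording <- function(rec, path, digits = 17) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", rec$fs),
    sprintf("# labels=%s", paste(rec$labels, collapse = ",")),
    sprintf("# start_time=%.10g", rec$start_time)
  ), con)
  fmt <- sprintf("%%.%dg", digits)
  lines <- apply(rec$data, 2, function(col) paste(sprintf(fmt, col), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Write a fractal-dimension time-course to CSV
#'
#' Long format: one row per (window, component) with columns
#' `time_s, component_id, fd, fd_sd`. Window geometry is stored in
#' `#` header lines so that [read_fd_timecourse()] reproduces the object
#' exactly (values are written with 17 significant digits).
#'
#' @param tc an `fd_timecourse` object from [fd_timecourse()].
#' @param path output CSV path.
#' @export
write_fd_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "fd_timecourse"))
  if (length(tc$times) < 1L) stop_param("empty time-course")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_data("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("# win_len=%d", tc$win_len),
    sprintf("# overlap=%.10g", tc$overlap),
    sprintf("# fs=%.10g", tc$fs)
  ), con)
  writeLines("time_s,component_id,fd,fd_sd", con)
  for (w in seq_along(tc$times)) {
    for (c_i in seq_len(nrow(tc$fd))) {
      writeLines(sprintf("%.17g,%s,%.17g,%.17g",
                         tc$times[w], tc$component_ids[c_i],
                         tc$fd[c_i, w], tc$fd_sd[c_i, w]), con)
    }
  }
  invisible(path)
}

#' Read a fractal-dimension time-course written by [write_fd_timecourse()]
#' @param path CSV path.
#' @return An `fd_timecourse` object.
#' @export
read_fd_timecourse <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  fields <- csv_header_fields(path)
  dat <- utils::read.table(path, sep = ",", header = TRUE, comment.char = "#",
                           colClasses = c("numeric", "character", "numeric", "numeric"))
  ids <- unique(dat$component_id)
  times <- unique(dat$time_s)
  fd <- matrix(NA_real_, nrow = length(ids), ncol = length(times),
               dimnames = list(ids, NULL))
  fd_sd <- fd
  wi <- match(dat$time_s, times)
  ci <- match(dat$component_id, ids)
  fd[cbind(ci, wi)] <- dat$fd
  fd_sd[cbind(ci, wi)] <- dat$fd_sd
  new_fd_timecourse(
    times = times, fd = fd, fd_sd = fd_sd,
    win_len = as.integer(fields$win_len %||% NA),
    overlap = as.numeric(fields$overlap %||% NA),
    fs = as.numeric(fields$fs %||% NA),
    component_ids = ids
  )
}

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) reader/writer, 16-bit integer samples.
# Physical values are used throughout; the digital<->physical calibration is
# the standard linear map from (dig_min, dig_max) to (phys_min, phys_max).

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Uses 1-second data records, so the sampling rate must be a whole number.
#' Each channel is scaled to the full 16-bit digital range of its own
#' physical min/max; values therefore round-trip within one quantization
#' step. If the signal length is not a whole number of records the tail is
#' zero-padded (with a warning).
#'
#' @param rec an [recording()] object with integer `fs`.
#' @param path output `.edf` path.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_config("EDF writer requires an integer sampling rate (1 s records)")
  fs <- as.integer(round(fs))
  nc <- n_channels(rec)
  ns <- n_samples(rec)
  n_rec <- ceiling(ns / fs)
  X <- rec$data
  if (n_rec * fs > ns) {
    warning("EDF: padding final record with zeros (", n_rec * fs - ns, " samples)")
    X <- cbind(X, matrix(0, nc, n_rec * fs - ns))
  }
  pmin_ <- apply(X, 1, min)
  pmax_ <- apply(X, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1   # avoid zero calibration span
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nc
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(nc, 4)
  )
  sig <- paste0(
    paste(edf_pad(rec$labels, 16), collapse = ""),
    paste(edf_pad(rep("", nc), 80), collapse = ""),
    paste(edf_pad(rep("uV", nc), 8), collapse = ""),
    paste(edf_pad(formatC(pmin_, format = "g", digits = 7), 8), collapse = ""),
    paste(edf_pad(formatC(pmax_, format = "g", digits = 7), 8), collapse = ""),
    paste(edf_pad(rep(dmin, nc), 8), collapse = ""),
    paste(edf_pad(rep(dmax, nc), 8), collapse = ""),
    paste(edf_pad(rep("", nc), 80), collapse = ""),
    paste(edf_pad(rep(fs, nc), 8), collapse = ""),
    paste(edf_pad(rep("", nc), 32), collapse = "")
  )
  writeChar(paste0(header, sig), con, eos = NULL, useBytes = TRUE)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nc)) {
      dig <- as.integer(round((X[ch, cols] - pmin_[ch]) * scale[ch]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' Parses the fixed-layout EDF header, reads all data records, and applies
#' each signal's physical calibration. All signals must share one sampling
#' rate (the loader targets ordinary uniform EEG/ECG recordings, not
#' mixed-rate or annotated EDF+ files).
#'
#' @param path `.edf` file path.
#' @return An [recording()] object.
#' @export
read_edf <- function(path) {
  con <- tryCatch(file(path, "rb"),
                  error = function(e) stop_data("cannot open EDF file: ", path))
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0L || nchar(out, type = "bytes") < n)
      stop_data("truncated EDF header")
    out
  }
  rd(8)                              # version
  rd(80); rd(80); rd(8); rd(8)       # patient, recording, date, time
  as.numeric(rd(8))                  # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  nc <- as.integer(trimws(rd(4)))
  if (is.na(nc) || nc < 1L || is.na(n_rec) || n_rec < 1L)
    stop_data("invalid EDF header (signal/record counts)")
  rdv <- function(w) vapply(seq_len(nc), function(i) trimws(rd(w)), "")
  labels <- rdv(16)
  rdv(80)                            # transducer
  rdv(8)                             # physical dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                            # prefiltering
  spr <- as.integer(rdv(8))          # samples per record, per signal
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop_data("EDF with mixed per-signal sampling rates is not supported")
  fs <- spr[1] / rec_dur
  total <- n_rec * sum(spr)
  dig <- readBin(con, integer(), n = total, size = 2L, endian = "little")
  if (length(dig) < total) stop_data("truncated EDF data section")
  X <- matrix(0, nrow = nc, ncol = n_rec * spr[1])
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      seg <- dig[(idx + 1L):(idx + spr[ch])]
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      X[ch, cols] <- pmin_[ch] +
        (seg - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      idx <- idx + spr[ch]
    }
  }
  if (!all(is.finite(X))) stop_data("EDF decodes to non-finite samples")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  recording(X, fs = fs, labels = labels)
}
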
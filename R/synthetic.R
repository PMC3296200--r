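# Seeded synthetic-signal generators with ground truth attached. These stand
# in for clinical recordings in calibration and verification: every generator
# is a pure function of (parameters, seed).

# fGn autocovariance at lag h for Hurst exponent H (unit variance).
fgn_acf <- function(h, H) {
  0.5 * (abs(h + 1)^(2 * H) - 2 * abs(h)^(2 * H) + abs(h - 1)^(2 * H))
}

# Circulant-embedding fGn synthesis for arbitrary n (exact in distribution).
# Consumes the current RNG stream; callers wrap it in with_seed().
fgn_core <- function(H, n) {
  m <- 2L * n
  gam <- fgn_acf(0:n, H)
  circ <- c(gam[1:n], gam[n + 1L], gam[n:2L])   # length 2n, symmetric
  eig <- Re(stats::fft(circ))
  eig[eig < 0] <- 0                      # clip tiny negative rounding
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  y <- stats::fft(sqrt(eig) * z)
  Re(y)[seq_len(n)] / sqrt(m)
}

#' Generate fractional Gaussian noise with known Hurst exponent
#'
#' Exact stationary fGn via circulant embedding of the autocovariance
#' (spectral synthesis). The cumulative sum of the output is fractional
#' Brownian motion with theoretical Higuchi fractal dimension `2 - H`,
#' which is what the estimator-calibration tests rely on.
#'
#' @param H Hurst exponent, in (0, 1).
#' @param n series length; a power of 2.
#' @param seed RNG seed.
#' @return List with `x` (the series) and `truth` (kind, parameters,
#'   `fd_fbm = 2 - H` for the integrated series, seed).
#' @export
gen_fgn <- function(H, n, seed = 1L) {
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1)
    stop_param("Hurst exponent H must lie strictly in (0, 1)")
  if (!is_pow2(n)) stop_param("n must be a power of 2 for the spectral method")
  x <- with_seed(seed, fgn_core(H, as.integer(n)))
  list(x = x,
       truth = list(kind = "fgn", params = list(H = H, n = n), seed = seed,
                    fd_fbm = 2 - H))
}

#' Generate fractional Brownian motion (cumulative fGn)
#'
#' @inheritParams gen_fgn
#' @return List with `x` (the fBm path) and `truth` including the
#'   theoretical Higuchi fractal dimension `fd_theory = 2 - H`.
#' @export
gen_fbm <- function(H, n, seed = 1L) {
  g <- gen_fgn(H, n, seed)
  list(x = cumsum(g$x),
       truth = list(kind = "fbm", params = list(H = H, n = n), seed = seed,
                    fd_theory = 2 - H))
}

# 1/f ("pink") noise by spectral shaping of white noise; unit variance.
pink_core <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))              # keep DC finite, zeroed below
  W <- W / sqrt(pmin(f, n - f + 1))
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-variance Laplace (double-exponential) noise.
laplace_core <- function(n) {
  (stats::rexp(n) - stats::rexp(n)) / sqrt(2)
}

# One synthetic source series of unit variance; consumes the RNG stream.
source_core <- function(kind, n, fs) {
  switch(kind,
    laplace = laplace_core(n),
    uniform = (stats::runif(n) - 0.5) * sqrt(12),
    white   = stats::rnorm(n),
    pink    = pink_core(n),
    sine    = {
      # delta band: rhythms whose period exceeds the largest Higuchi stride
      # (k_max = 64 samples at 128 Hz, i.e. f < 2 Hz) measure a low, stable
      # FD; faster narrowband rhythms alias to spuriously high FD there
      f <- stats::runif(1, 1.0, 1.6)
      sqrt(2) * sin(2 * pi * f * seq_len(n) / fs + stats::runif(1, 0, 2 * pi))
    },
    sawtooth = {
      ph <- (seq_len(n) * 3 / fs) %% 1          # 3 Hz ramp
      s <- 2 * ph - 1
      s / stats::sd(s)
    },
    fbm = {
      x <- cumsum(fgn_core(0.5, n))
      x / stats::sd(x)
    },
    stop_param("unknown source kind: ", kind)
  )
}

#' Generate a linear mixture of independent non-Gaussian sources
#'
#' Realizes the blind-source-separation forward model `X = A S` (optionally
#' plus white sensor noise at a given SNR), keeping the true sources and
#' mixing matrix as ground truth for separation benchmarks.
#'
#' @param source_kinds character vector of source types; one of `"laplace"`,
#'   `"uniform"`, `"sine"`, `"sawtooth"`, `"white"`, `"pink"`, `"fbm"`. At
#'   most one source should be Gaussian for the model to be identifiable.
#' @param A mixing matrix, `n_channels x n_sources` with
#'   `n_channels >= n_sources`.
#' @param n number of samples.
#' @param fs sampling rate, Hz (default 128).
#' @param noise_snr_db optional per-recording SNR of added white noise, dB.
#' @param seed RNG seed.
#' @return List with `recording` (an [recording()]) and `truth`
#'   (`S` true sources, `A`, kinds, seed).
#' @export
gen_mixture <- function(source_kinds, A, n, fs = 128, noise_snr_db = NULL,
                        seed = 1L) {
  A <- as.matrix(A)
  if (ncol(A) != length(source_kinds))
    stop_param("ncol(A) must equal the number of sources")
  if (nrow(A) < ncol(A))
    stop_param("need at least as many channels as sources (rows(A) >= cols(A))")
  with_seed(seed, {
    S <- t(vapply(source_kinds, source_core, numeric(n), n = n, fs = fs))
    X <- A %*% S
    if (!is.null(noise_snr_db)) X <- add_white_noise(X, noise_snr_db)
    list(recording = recording(X, fs = fs),
         truth = list(kind = "mixture", S = S, A = A, kinds = source_kinds,
                      seed = seed, noise_snr_db = noise_snr_db))
  })
}

# Add white Gaussian noise at the requested recording-level SNR (dB).
add_white_noise <- function(X, snr_db) {
  p_sig <- mean(X^2)
  p_noise <- p_sig / 10^(snr_db / 10)
  X + matrix(stats::rnorm(length(X), sd = sqrt(p_noise)), nrow(X))
}

# Random square mixing matrix with condition number below `max_cond`.
random_mixing <- function(d, max_cond = 10) {
  repeat {
    A <- matrix(stats::rnorm(d * d), d)
    sv <- svd(A)$d
    if (sv[1] / sv[d] < max_cond) return(A)
  }
}

#' Generate a seizure-like multichannel recording with known onset
#'
#' Emulates the qualitative structure of an epileptic scalp recording: one
#' latent "epileptic" source is chaotic broadband noise (fGn, `H = 0.3`,
#' high fractal dimension) preictally, then crossfades linearly over
#' `transition_s` seconds into a periodic high-amplitude 3 Hz spike train
#' (low fractal dimension), holds the pure ictal morphology for
#' `plateau_s` seconds, and recovers back to broadband over `recovery_s`
#' seconds - so the windowed FD of that source declines before the onset,
#' is minimal at the onset, and recovers after it. The remaining sources
#' are rhythmic background (slow 2-4 Hz waves plus a little pink noise),
#' whose fractal dimension stays well below the chaotic preictal level at
#' the default measurement scale. All sources
#' are mixed by a random well-conditioned matrix; optional white sensor
#' noise is added at `noise_snr_db`.
#'
#' Defaults mirror a roughly 21-minute recording whose seizure begins at
#' 848 s, sampled at 128 Hz so one 2048-sample analysis window spans 16 s.
#'
#' @param fs sampling rate, Hz.
#' @param duration_s total duration, seconds.
#' @param onset_s seizure onset, seconds (`0 < onset_s < duration_s`).
#' @param n_channels number of channels (= number of latent sources).
#' @param seed RNG seed.
#' @param noise_snr_db optional white-noise SNR, dB.
#' @param transition_s preictal FD-decline ramp length, seconds.
#' @param plateau_s pure-ictal spike-train plateau, seconds.
#' @param recovery_s postictal recovery ramp, seconds.
#' @param spike_hz spike repetition rate, Hz.
#' @param wave_hz ictal slow-wave fundamental, Hz.
#' @param spike_amp ictal amplitude relative to the preictal background.
#' @return List with `recording` and `truth` (`onset_s`, `onset_sample
#'   = round(onset_s * fs)`, `source_index` of the epileptic source, `A`,
#'   `S`, parameters, seed).
#' @export
gen_seizure_recording <- function(fs = 128, duration_s = 1260, onset_s = 848,
                                  n_channels = 4L, seed = 1L,
                                  noise_snr_db = NULL, transition_s = 120,
                                  plateau_s = 16, recovery_s = 60,
                                  spike_hz = 3, wave_hz = 1, spike_amp = 3) {
  if (onset_s <= 0 || onset_s >= duration_s)
    stop_param("need 0 < onset_s < duration_s")
  n <- round(duration_s * fs)
  if (n < 2L * 2048L)
    stop_param("recording too short for at least two analysis windows")
  if (n_channels < 1L) stop_param("n_channels must be >= 1")
  with_seed(seed, {
    bg <- fgn_core(0.3, n)
    bg <- bg / stats::sd(bg)
    # Ictal morphology: sawtooth spike complexes riding a slow wave - the
    # spike train repeats at `spike_hz`, the fundamental at `wave_hz`. The
    # slow fundamental is what gives the ictal segment its genuinely low
    # Higuchi FD at the default stride range; very narrow impulses or a
    # fast fundamental would instead alias to a high FD and are avoided.
    t_all <- seq_len(n) / fs
    saw <- 2 * ((seq_len(n) * spike_hz / fs) %% 1) - 1
    spike <- sin(2 * pi * wave_hz * t_all) + 0.4 * saw
    spike <- spike - mean(spike)
    spike <- spike / stats::sd(spike) * spike_amp
    t_s <- (seq_len(n) - 1) / fs
    # Crossfade weight: cubic ramps, so the fractal dimension declines
    # gradually through most of the transition and falls sharply just
    # before the onset (and mirrors that on recovery). This keeps the FD
    # minimum localized at the onset rather than smeared across the ramps.
    w <- numeric(n)
    ramp_in <- t_s >= onset_s - transition_s & t_s < onset_s
    w[ramp_in] <- ((t_s[ramp_in] - (onset_s - transition_s)) / transition_s)^3
    w[t_s >= onset_s & t_s < onset_s + plateau_s] <- 1
    ramp_out <- t_s >= onset_s + plateau_s & t_s < onset_s + plateau_s + recovery_s
    w[ramp_out] <- (1 - (t_s[ramp_out] - (onset_s + plateau_s)) / recovery_s)^3
    epi <- (1 - w) * bg + w * spike
    S <- matrix(0, n_channels, n)
    S[1, ] <- epi
    for (j in seq_len(n_channels)[-1]) {
      s <- source_core("sine", n, fs) + 0.05 * pink_core(n)
      S[j, ] <- s / stats::sd(s)
    }
    A <- if (n_channels > 1L) random_mixing(n_channels) else matrix(1, 1, 1)
    X <- A %*% S
    if (!is.null(noise_snr_db)) X <- add_white_noise(X, noise_snr_db)
    list(
      recording = recording(X, fs = fs),
      truth = list(kind = "seizure", onset_s = onset_s,
                   onset_sample = round(onset_s * fs), source_index = 1L,
                   A = A, S = S, seed = seed,
                   params = list(fs = fs, duration_s = duration_s,
                                 n_channels = n_channels,
                                 noise_snr_db = noise_snr_db,
                                 transition_s = transition_s,
                                 plateau_s = plateau_s,
                                 recovery_s = recovery_s,
                                 spike_hz = spike_hz, wave_hz = wave_hz,
                                 spike_amp = spike_amp))
    )
  })
}
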
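# Independent brute-force oracles, written as plain index loops so they share
# no code path with the implementation they check.

# Higuchi curve length by direct evaluation of the defining sum.
brute_curve_length <- function(X, m, k) {
  N <- length(X)
  p <- floor((N - m) / k)
  total <- 0
  for (i in seq_len(p)) {
    total <- total + abs(X[m + i * k] - X[m + (i - 1) * k])
  }
  (1 / k) * total * (N - 1) / (p * k)
}

# Sliding-window count by explicit enumeration of candidate starts.
brute_window_count <- function(n_samples, win_len, step) {
  count <- 0
  start <- 0
  while (start + win_len <= n_samples) {
    count <- count + 1
    start <- start + step
  }
  count
}

# One-unit FastICA update by per-column summation.
brute_one_unit_update <- function(w, Xw, g, gprime) {
  d <- nrow(Xw); n <- ncol(Xw)
  term1 <- numeric(d)
  term2 <- 0
  for (j in seq_len(n)) {
    y <- sum(w * Xw[, j])
    term1 <- term1 + Xw[, j] * g(y)
    term2 <- term2 + gprime(y)
  }
  term1 / n - (term2 / n) * w
}

# Match estimated sources to true sources greedily by |Pearson r|; returns the
# per-true-source best absolute correlation.
match_abs_cor <- function(S_est, S_true) {
  cc <- abs(stats::cor(t(S_est), t(S_true)))
  apply(cc, 2, max)
}

seizure_step_s <- function(win_len = 2048, overlap = 0.5, fs = 128) {
  win_len * (1 - overlap) / fs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
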
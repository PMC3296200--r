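#' Stride-k subsequence of a time series
#'
#' From a series of length `N`, the Higuchi construction forms `k` new
#' series, one per starting phase `m = 1..k`, taking every `k`-th sample:
#' indices `m, m+k, m+2k, ..., m + floor((N-m)/k)*k` (1-based).
#'
#' @param N series length.
#' @param m starting index, `1 <= m <= k`.
#' @param k stride (time interval), `k <= N - 1`.
#' @return Integer vector of 1-based indices.
#' @examples
#' subsequence_indices(1000, m = 1, k = 4)[1:3]  # 1 5 9
#' @export
subsequence_indices <- function(N, m, k) {
  if (k < 1 || k >= N) stop_param("need 1 <= k <= N-1")
  if (m < 1 || m > k) stop_param("need 1 <= m <= k")
  seq.int(m, by = k, length.out = floor((N - m) / k) + 1L)
}

#' Higuchi curve length of one stride-k subsequence
#'
#' The normalized length of the phase-`m`, stride-`k` subsequence:
#' `L_m(k) = (1/k) * sum_{i=1..p} |X(m+ik) - X(m+(i-1)k)| * (N-1)/(p*k)`
#' with `p = floor((N-m)/k)`. The factor `(N-1)/(p*k)` normalizes for the
#' fraction of the series the subsequence covers, so lengths at different
#' `k` are comparable.
#'
#' @param X numeric series.
#' @param m starting index (1-based).
#' @param k stride.
#' @return Scalar length `L_m(k)` (0 for a constant series).
#' @export
curve_length <- function(X, m, k) {
  N <- length(X)
  idx <- subsequence_indices(N, m, k)
  p <- length(idx) - 1L
  if (p < 1L) stop_param("subsequence has fewer than 2 points (m=", m, ", k=", k, ")")
  sum(abs(diff(X[idx]))) * (N - 1) / (p * k) / k
}

#' Mean Higuchi curve length at stride k
#'
#' Arithmetic mean of `L_m(k)` over the `k` starting phases `m = 1..k`.
#'
#' @inheritParams curve_length
#' @return Scalar `L(k)`.
#' @export
mean_length <- function(X, k) {
  mean(vapply(seq_len(k), function(m) curve_length(X, m, k), 0.0))
}

# All L(k) for k in k_values, sharing the lag-differences across phases.
higuchi_lengths <- function(X, k_values) {
  N <- length(X)
  vapply(k_values, function(k) {
    d <- abs(X[(1L + k):N] - X[1:(N - k)])
    Lm <- vapply(seq_len(k), function(m) {
      pos <- seq.int(m, N - k, by = k)
      p <- length(pos)
      sum(d[pos]) * (N - 1) / (p * k) / k
    }, 0.0)
    mean(Lm)
  }, 0.0)
}

#' Higuchi fractal dimension of a time series
#'
#' Estimates the fractal dimension directly in the time domain from the
#' scaling `L(k) ~ k^(-Df)` of mean curve lengths: the slope of the
#' least-squares regression of `y_k = ln L(k)` on `x_k = ln(1/k)` over
#' `k = 1..k_max`. A smooth simple curve has `Df = 1`; a curve that nearly
#' fills the plane approaches `Df = 2`. Closed-form least-squares formulas
#' give the slope `Df`, intercept `b`, and their standard deviations
#' `S_Df`, `S_b` (the usual regression standard errors; `NaN` when only
#' two `k` values are used, since the residual variance has `n - 2`
#' degrees of freedom).
#'
#' `Df` is invariant under amplitude scaling of `X` (scaling multiplies
#' every `L(k)` by the same factor, shifting only the intercept) and under
#' additive offsets (lengths are built from first differences).
#'
#' @param X numeric series, non-constant, length `>= k_max + 1`.
#' @param k_max largest stride; all of `k = 1..k_max` enter the regression
#'   unless `k_values` is given. Default 64, sized for windows of around
#'   2048 samples (about 1.8 decades of scale with >= 32 points per
#'   subsequence).
#' @param k_values optional explicit subset of strides (>= 2 values).
#' @return Object of class `higuchi_fd`: `Df`, `b`, `S_Df`, `S_b`,
#'   `k_values`, `L` (mean lengths per k), `n` (number of k values), `N`.
#' @examples
#' fit <- higuchi_fd(seq_len(1000), k_max = 8)  # a straight line: Df = 1
#' coef(fit)
#' @export
higuchi_fd <- function(X, k_max = 64L, k_values = NULL) {
  N <- length(X)
  if (is.null(k_values)) {
    if (k_max < 2L) stop_param("k_max must be >= 2")
    k_values <- seq_len(k_max)
  }
  k_values <- as.integer(k_values)
  if (length(k_values) < 2L) stop_param("need at least 2 k values")
  if (max(k_values) >= N) stop_param("series too short: need N >= max(k) + 1")
  L <- higuchi_lengths(as.numeric(X), k_values)
  if (any(L <= 0))
    stop_data("degenerate input: constant (sub)series gives zero curve length, ",
              "fractal dimension undefined")
  x <- log(1 / k_values)
  y <- log(L)
  n <- length(k_values)
  Sx <- sum(x); Sy <- sum(y); Sxy <- sum(x * y); Sxx <- sum(x^2); Syy <- sum(y^2)
  den <- n * Sxx - Sx^2
  Df <- (n * Sxy - Sx * Sy) / den
  b <- (Sy - Df * Sx) / n
  if (n > 2L) {
    sse <- max(Syy - Df * Sxy - b * Sy, 0)    # clamp tiny negative rounding
    S_Df <- sqrt(n * sse / ((n - 2) * den))
    S_b <- sqrt(S_Df^2 * Sxx / n)
  } else {
    S_Df <- NaN
    S_b <- NaN
  }
  structure(
    list(Df = Df, b = b, S_Df = S_Df, S_b = S_b,
         k_values = k_values, L = L, n = n, N = N),
    class = "higuchi_fd"
  )
}

#' @export
print.higuchi_fd <- function(x, ...) {
  cat(sprintf("<higuchi_fd> Df = %.6f (SD %.3g), b = %.4f (SD %.3g)\n",
              x$Df, x$S_Df, x$b, x$S_b))
  cat(sprintf("  N = %d samples, k = %d..%d (%d values)\n",
              x$N, min(x$k_values), max(x$k_values), x$n))
  invisible(x)
}

#' @export
coef.higuchi_fd <- function(object, ...) {
  c(Df = object$Df, b = object$b)
}

#' @export
summary.higuchi_fd <- function(object, ...) {
  out <- data.frame(k = object$k_values, L = object$L,
                    log_inv_k = log(1 / object$k_values), log_L = log(object$L))
  cat(sprintf("Higuchi fractal dimension: Df = %.6f +/- %.3g (intercept %.4f +/- %.3g)\n\n",
              object$Df, object$S_Df, object$b, object$S_b))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.higuchi_fd <- function(x, ...) {
  lx <- log(1 / x$k_values); ly <- log(x$L)
  graphics::plot(lx, ly, xlab = "ln(1/k)", ylab = "ln L(k)",
                 main = sprintf("Higuchi scaling, Df = %.3f", x$Df), ...)
  graphics::abline(x$b, x$Df, col = "red3")
  invisible(x)
}
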
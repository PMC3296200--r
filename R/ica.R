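#' Whiten centered multichannel data
#'
#' Linear transform making the channel covariance the identity, computed by
#' eigenvalue decomposition of the sample covariance: with `cov(X) = E D E'`,
#' the whitened data are `Xw = D^{-1/2} E' X`. Whitening is the standard
#' precondition for FastICA: after it the mixing matrix to be estimated is
#' orthogonal. `var_keep < 1` performs dimension reduction by keeping the
#' smallest leading set of eigenvalues whose cumulative variance fraction
#' reaches `var_keep`.
#'
#' @param Xc centered numeric matrix (channels x samples; row means zero).
#' @param var_keep fraction of total variance to retain, in (0, 1].
#' @return An object of class `whitening`: list with `Xw` (whitened data,
#'   `n_comp x n_samples`), `V` (whitening matrix, `n_comp x n_channels`),
#'   `dewhiten` (its pseudo-inverse, `n_channels x n_comp`) and `eigvals`
#'   (retained covariance eigenvalues).
#' @export
whiten <- function(Xc, var_keep = 1.0) {
  if (is.vector(Xc)) Xc <- matrix(Xc, nrow = 1)
  d <- nrow(Xc); n <- ncol(Xc)
  if (n <= d) stop_param("need more samples than channels to whiten")
  if (!(var_keep > 0 && var_keep <= 1)) stop_param("var_keep must be in (0, 1]")
  rms <- sqrt(rowMeans(Xc^2))
  if (any(abs(rowMeans(Xc)) > 1e-6 * pmax(rms, .Machine$double.eps)))
    stop_param("whiten() expects row-centered data; call center_rows() first")
  C <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  d_all <- eg$values
  if (var_keep >= 1 && any(d_all <= 1e-10 * max(d_all)))
    stop_data("covariance is (near) rank-deficient; reduce dimension with var_keep < 1")
  frac <- cumsum(d_all) / sum(d_all)
  r <- which(frac >= var_keep - 1e-12)[1]
  keep <- seq_len(r)
  E <- eg$vectors[, keep, drop = FALSE]
  dv <- d_all[keep]
  V <- diag(1 / sqrt(dv), r) %*% t(E)
  structure(
    list(Xw = V %*% Xc, V = V, dewhiten = E %*% diag(sqrt(dv), r), eigvals = dv),
    class = "whitening"
  )
}

#' FastICA contrast nonlinearity
#'
#' The three standard one-unit contrast derivatives: `g1(y) = tanh(a1*y)`
#' (robust general-purpose default), `g2(y) = y*exp(-y^2/2)` (for highly
#' super-Gaussian sources) and `g3(y) = 4*y^3` (kurtosis-based). Each is
#' odd; its analytic derivative is carried alongside for the Newton-type
#' fixed-point update.
#'
#' @param name one of `"g1"`, `"g2"`, `"g3"`.
#' @param a1 slope parameter of `g1`, conventionally 1.
#' @return An object of class `ica_nonlinearity` with elements `name`,
#'   `a1`, `g` and `gprime`.
#' @export
ica_nonlinearity <- function(name = c("g1", "g2", "g3"), a1 = 1.0) {
  name <- match.arg(name)
  fns <- switch(name,
    g1 = list(g = function(y) tanh(a1 * y),
              gprime = function(y) a1 * (1 - tanh(a1 * y)^2)),
    g2 = list(g = function(y) y * exp(-y^2 / 2),
              gprime = function(y) (1 - y^2) * exp(-y^2 / 2)),
    g3 = list(g = function(y) 4 * y^3,
              gprime = function(y) 12 * y^2)
  )
  structure(list(name = name, a1 = a1, g = fns$g, gprime = fns$gprime),
            class = "ica_nonlinearity")
}

#' One FastICA fixed-point (Newton) update
#'
#' For a unit weight vector `w` and whitened data `Xw`, returns
#' `E{ x g(w'x) } - E{ g'(w'x) } w`, with expectations taken as sample
#' means over columns. Exposed separately so the update can be verified
#' against direct per-column summation.
#'
#' @param w numeric weight vector, unit norm.
#' @param Xw whitened data matrix (rows = whitened dimensions).
#' @param nl an [ica_nonlinearity()].
#' @return Updated (not yet normalized) weight vector.
#' @export
one_unit_update <- function(w, Xw, nl = ica_nonlinearity("g1")) {
  y <- drop(crossprod(w, Xw))
  drop(Xw %*% nl$g(y)) / ncol(Xw) - mean(nl$gprime(y)) * w
}

#' FastICA by deflation
#'
#' Estimates independent components from whitened data one unit at a time:
#' each unit iterates the fixed-point update ([one_unit_update()]),
#' is decorrelated against previously extracted units by Gram-Schmidt
#' projection, renormalized, and declared converged when
#' `|<w_new, w_old>| > 1 - tol`. Initial weights are random unit vectors
#' from the seeded RNG, so results are reproducible bit-for-bit for a fixed
#' seed. The sign of each component is fixed by flipping it so that its
#' largest-magnitude sample is positive.
#'
#' @param Xw whitened data (`n_comp_max x n_samples`), e.g. `whiten(...)$Xw`.
#' @param n_comp number of components to extract (default all rows of `Xw`).
#' @param nl an [ica_nonlinearity()]; default `g1` with `a1 = 1`.
#' @param tol convergence tolerance on `1 - |<w_new, w_old>|`.
#' @param max_iter maximum fixed-point iterations per unit; units that do
#'   not converge are flagged (with a warning) but still returned.
#' @param seed RNG seed for the weight initialization (NULL: current RNG).
#' @param whitening optional `whitening` object; when given, the estimated
#'   mixing matrix is mapped back to channel space.
#' @return An object of class `ica_result`: `W` (unmixing rows, orthonormal),
#'   `S` (`= W %*% Xw`, the estimated sources), `A_hat` (estimated mixing
#'   matrix, channel space when `whitening` is supplied, else whitened
#'   space), `n_iter`, `converged`.
#' @export
fastica <- function(Xw, n_comp = nrow(Xw), nl = ica_nonlinearity("g1"),
                    tol = 1e-6, max_iter = 200L, seed = NULL,
                    whitening = NULL) {
  if (inherits(Xw, "whitening")) {
    whitening <- Xw
    Xw <- Xw$Xw
  }
  d <- nrow(Xw)
  if (n_comp < 1L || n_comp > d)
    stop_param("n_comp must be between 1 and nrow(Xw) = ", d)
  W <- matrix(0, n_comp, d)
  n_iter <- integer(n_comp)
  converged <- logical(n_comp)
  with_seed(seed, {
    for (i in seq_len(n_comp)) {
      w <- stats::rnorm(d)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        w_old <- w
        w <- one_unit_update(w, Xw, nl)
        if (i > 1L) {
          Wp <- W[seq_len(i - 1L), , drop = FALSE]
          w <- w - drop(crossprod(Wp, Wp %*% w))
        }
        nw <- sqrt(sum(w^2))
        if (nw < .Machine$double.eps)
          stop_data("FastICA weight collapsed to zero (degenerate input)")
        w <- w / nw
        n_iter[i] <- it
        if (abs(sum(w * w_old)) > 1 - tol) { converged[i] <- TRUE; break }
      }
      W[i, ] <- w
    }
  })
  if (!all(converged))
    warning("FastICA: ", sum(!converged), " unit(s) did not converge in ",
            max_iter, " iterations")
  S <- W %*% Xw
  for (i in seq_len(n_comp)) {            # deterministic sign convention
    peak <- which.max(abs(S[i, ]))
    if (S[i, peak] < 0) { S[i, ] <- -S[i, ]; W[i, ] <- -W[i, ] }
  }
  A_hat <- if (!is.null(whitening)) whitening$dewhiten %*% t(W) else t(W)
  structure(
    list(W = W, S = S, A_hat = A_hat, n_iter = n_iter, converged = converged,
         nonlinearity = nl$name),
    class = "ica_result"
  )
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %d component(s), nonlinearity %s\n",
              nrow(x$W), x$nonlinearity))
  cat("  iterations:", paste(x$n_iter, collapse = ", "),
      "| converged:", paste(x$converged, collapse = ", "), "\n")
  invisible(x)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between a true mixing matrix
#' and its estimate, based on the gain matrix `P = pinv(A_hat) %*% A`.
#' Normalized to `[0, 1]`; 0 means perfect separation up to permutation and
#' scaling.
#'
#' @param A true mixing matrix.
#' @param A_hat estimated mixing matrix (same shape).
#' @return Scalar index in `[0, 1]`.
#' @export
amari_index <- function(A, A_hat) {
  P <- abs(pinv(A_hat) %*% A)
  m <- nrow(P)
  row_term <- sum(rowSums(P / apply(P, 1, max)) - 1)
  col_term <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (row_term + col_term) / (2 * m * (m - 1))
}

pinv <- function(A, rtol = 1e-12) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
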
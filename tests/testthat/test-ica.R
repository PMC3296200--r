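test_that("whitening produces identity covariance and a valid transform", {
  set.seed(1)
  A <- matrix(c(2, 1, 1, 2), 2)        # covariance of x = A z is A %*% t(A)
  Xc <- center_rows(A %*% matrix(rnorm(2 * 50000), 2))
  wh <- whiten(Xc)
  Cw <- tcrossprod(wh$Xw) / (ncol(wh$Xw) - 1)
  expect_lt(max(abs(Cw - diag(2))), 1e-8)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  expect_lt(max(abs(wh$V %*% C %*% t(wh$V) - diag(2))), 1e-8)
  # dewhitening inverts the whitening map on the retained subspace
  expect_lt(max(abs(wh$dewhiten %*% wh$V %*% C - C)), 1e-6)
})

test_that("already-white input stays white and V is close to a rotation", {
  set.seed(2)
  Xc <- center_rows(matrix(rnorm(2 * 60000), 2))
  wh <- whiten(Xc)
  Cw <- tcrossprod(wh$Xw) / (ncol(wh$Xw) - 1)
  expect_lt(max(abs(Cw - diag(2))), 1e-8)
  expect_lt(max(abs(crossprod(wh$V) - diag(2))), 0.05)
})

test_that("rank-deficient input raises a dimension-reduction error", {
  set.seed(3)
  x <- rnorm(1000)
  X <- center_rows(rbind(x, x))
  expect_error(whiten(X), class = "epifd_data_error")
  # but var_keep < 1 recovers a 1-D whitened representation
  wh <- whiten(X, var_keep = 0.99)
  expect_equal(nrow(wh$Xw), 1L)
})

test_that("whiten validates its inputs", {
  expect_error(whiten(matrix(rnorm(20) + 10, 2)), class = "epifd_param_error")
  expect_error(whiten(center_rows(matrix(rnorm(20), 2)), var_keep = 0),
               class = "epifd_param_error")
})

test_that("nonlinearities are odd with correct derivatives", {
  y <- seq(-3, 3, by = 0.25)
  for (nm in c("g1", "g2", "g3")) {
    nl <- ica_nonlinearity(nm)
    expect_equal(nl$g(-y), -nl$g(y))
    num <- (nl$g(y + 1e-6) - nl$g(y - 1e-6)) / 2e-6
    expect_equal(nl$gprime(y), num, tolerance = 1e-5)
  }
  expect_equal(ica_nonlinearity("g1", a1 = 2)$g(0.5), tanh(1))
})

test_that("one-unit update matches the per-column summation oracle", {
  Xw <- matrix(c(1, 0, -1, 1, 2, 0, -2, -1), 2)   # columns (1,0),(-1,1),(2,0),(-2,-1)
  w <- c(1, 0)
  nl <- ica_nonlinearity("g3")
  got <- one_unit_update(w, Xw, nl)
  expect_equal(got, brute_one_unit_update(w, Xw, nl$g, nl$gprime),
               tolerance = 1e-12)
  expect_equal(got, c(4, 7))   # frozen hand evaluation
  # random instances against the oracle, all three contrasts
  set.seed(5)
  for (i in 1:20) {
    Xr <- matrix(rnorm(3 * 40), 3)
    wr <- rnorm(3); wr <- wr / sqrt(sum(wr^2))
    nlr <- ica_nonlinearity(sample(c("g1", "g2", "g3"), 1))
    expect_equal(one_unit_update(wr, Xr, nlr),
                 brute_one_unit_update(wr, Xr, nlr$g, nlr$gprime),
                 tolerance = 1e-12)
  }
  # zero data: update reduces to -g'(0) * w
  Z <- matrix(0, 2, 10)
  expect_equal(one_unit_update(w, Z, ica_nonlinearity("g1")), -1 * w)
})

test_that("fastica recovers independent Laplace sources up to sign/permutation", {
  g <- gen_mixture(c("laplace", "laplace"), A = matrix(c(1, 0.5, 0.5, 1), 2),
                   n = 20000, seed = 3)
  wh <- whiten(center_rows(g$recording$data))
  ic <- fastica(wh$Xw, seed = 7, whitening = wh)
  expect_true(all(match_abs_cor(ic$S, g$truth$S) >= 0.95))
  expect_lt(max(abs(tcrossprod(ic$W) - diag(2))), 1e-6)
  expect_equal(ic$S, ic$W %*% wh$Xw)
  expect_lt(amari_index(g$truth$A, ic$A_hat), 0.1)
})

test_that("a single non-Gaussian component is self-recovered", {
  set.seed(9)
  s <- laplace <- (rexp(30000) - rexp(30000)) / sqrt(2)
  Xw <- matrix(s / sd(s), 1)
  ic <- fastica(Xw, n_comp = 1, seed = 2)
  expect_gte(abs(cor(ic$S[1, ], s)), 0.99)
})

test_that("Gaussian-only sources keep W orthonormal despite unidentifiability", {
  set.seed(11)
  Xw <- whiten(center_rows(matrix(rnorm(2 * 20000), 2)))$Xw
  ic <- suppressWarnings(fastica(Xw, seed = 4, max_iter = 30))
  expect_lt(max(abs(tcrossprod(ic$W) - diag(2))), 1e-6)
})

test_that("fastica is bit-for-bit reproducible for a fixed seed", {
  g <- gen_mixture(c("laplace", "uniform"), A = diag(2), n = 5000, seed = 6)
  wh <- whiten(center_rows(g$recording$data))
  expect_identical(fastica(wh$Xw, seed = 123), fastica(wh$Xw, seed = 123))
})

test_that("sign convention makes each component's largest peak positive", {
  g <- gen_mixture(c("laplace", "sine"), A = matrix(c(1, .3, .4, 1), 2),
                   n = 8000, seed = 8)
  wh <- whiten(center_rows(g$recording$data))
  ic <- fastica(wh$Xw, seed = 1)
  for (i in 1:2) expect_gt(ic$S[i, which.max(abs(ic$S[i, ]))], 0)
})

test_that("estimates agree with scikit-learn's deflation FastICA", {
  g <- gen_mixture(c("laplace", "laplace"), A = matrix(c(1, 0.6, 0.4, 1), 2),
                   n = 20000, seed = 13)
  wh <- whiten(center_rows(g$recording$data))
  ic <- fastica(wh$Xw, seed = 5)
  csv_in <- tempfile(fileext = ".csv")
  csv_out <- tempfile(fileext = ".csv")
  write.table(t(wh$Xw), csv_in, sep = ",", row.names = FALSE, col.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.decomposition import FastICA",
    "X = np.loadtxt(sys.argv[1], delimiter=',')",
    "ica = FastICA(n_components=2, whiten=False, algorithm='deflation',",
    "              fun='logcosh', random_state=0, max_iter=400)",
    "S = ica.fit_transform(X)",
    "np.savetxt(sys.argv[2], S, delimiter=',')"
  ), py)
  res <- system2("python", c(py, csv_in, csv_out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(csv_out))
  S_sk <- t(as.matrix(read.csv(csv_out, header = FALSE)))
  expect_true(all(match_abs_cor(ic$S, S_sk) >= 0.95))
})

test_that("amari index is zero for permuted/scaled versions of A", {
  set.seed(15)
  A <- matrix(rnorm(9), 3)
  P <- A[, c(2, 3, 1)] %*% diag(c(2, -1, 0.5))
  expect_lt(amari_index(A, P), 1e-10)
  expect_gt(amari_index(A, matrix(rnorm(9), 3)), 0.05)
})
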
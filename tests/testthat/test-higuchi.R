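test_that("subsequence decomposition reproduces the worked k=4, N=1000 case", {
  s1 <- subsequence_indices(1000, m = 1, k = 4)
  expect_equal(s1[1:3], c(1, 5, 9))
  expect_equal(tail(s1, 1), 997)
  expect_length(s1, 250)
  s4 <- subsequence_indices(1000, m = 4, k = 4)
  expect_equal(s4[1:3], c(4, 8, 12))
  expect_equal(tail(s4, 1), 1000)
  expect_equal(subsequence_indices(9, 1, 1), 1:9)
  expect_error(subsequence_indices(10, m = 3, k = 2), class = "epifd_param_error")
  expect_error(subsequence_indices(10, m = 1, k = 10), class = "epifd_param_error")
})

test_that("curve lengths match hand evaluation and the ramp closed form", {
  expect_equal(curve_length(rep(2, 10), 1, 3), 0)
  # X=[1,3,2,5]: p=1, |X(3)-X(1)|=1, (1/2)*1*(3/2) = 0.75
  expect_equal(curve_length(c(1, 3, 2, 5), 1, 2), 0.75)
  # phase m=2: |X(4)-X(2)|=2, (1/2)*2*(3/2) = 1.5; mean over phases = 1.125
  expect_equal(curve_length(c(1, 3, 2, 5), 2, 2), 1.5)
  expect_equal(mean_length(c(1, 3, 2, 5), 2), 1.125)
  # linear ramp: every |diff| = k, sum telescopes, L_m(k) = (N-1)/k exactly
  N <- 500
  for (k in c(1, 3, 7)) {
    for (m in c(1, k)) expect_equal(curve_length(1:N, m, k), (N - 1) / k)
    expect_equal(mean_length(1:N, k), (N - 1) / k)
  }
  expect_equal(mean_length(c(2, 5, 1), 1), curve_length(c(2, 5, 1), 1, 1))
})

test_that("curve_length agrees with an explicit-loop oracle on random cases", {
  set.seed(42)
  for (i in 1:300) {
    N <- sample(10:200, 1)
    k <- sample(1:(N %/% 3), 1)
    m <- sample(1:k, 1)
    X <- rnorm(N)
    expect_equal(curve_length(X, m, k), brute_curve_length(X, m, k),
                 tolerance = 1e-12)
  }
})

test_that("a straight line has fractal dimension exactly 1", {
  fit <- higuchi_fd(1:1000, k_max = 8)
  expect_equal(fit$Df, 1, tolerance = 1e-9)
  # log-log points exactly collinear for the ramp
  resid <- log(fit$L) - (fit$b + fit$Df * log(1 / fit$k_values))
  expect_lt(max(abs(resid)), 1e-12)
  expect_equal(fit$L, (1000 - 1) / fit$k_values)
})

test_that("regression slope and standard errors match lm()", {
  x <- gen_fbm(0.5, 1024, seed = 5)$x
  fit <- higuchi_fd(x, k_max = 16)
  lmfit <- lm(log(fit$L) ~ I(log(1 / fit$k_values)))
  sm <- summary(lmfit)$coefficients
  expect_equal(fit$Df, unname(sm[2, 1]), tolerance = 1e-10)
  expect_equal(fit$b, unname(sm[1, 1]), tolerance = 1e-10)
  expect_equal(fit$S_Df, unname(sm[2, 2]), tolerance = 1e-8)
  expect_equal(fit$S_b, unname(sm[1, 2]), tolerance = 1e-8)
})

test_that("Df is invariant under scaling and offset; b shifts by ln(c)", {
  x <- gen_fbm(0.3, 2048, seed = 7)$x
  base <- higuchi_fd(x, k_max = 32)
  for (c_ in c(0.1, 1, 1000)) {
    sc <- higuchi_fd(c_ * x, k_max = 32)
    expect_equal(sc$Df, base$Df, tolerance = 1e-12)
    expect_equal(sc$b, base$b + log(c_), tolerance = 1e-9)
  }
  sh <- higuchi_fd(x + 100, k_max = 32)
  expect_equal(sh$Df, base$Df, tolerance = 1e-12)
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(higuchi_fd(rep(1, 100), k_max = 8), class = "epifd_data_error")
  expect_error(higuchi_fd(1:100, k_max = 1), class = "epifd_param_error")
  expect_error(higuchi_fd(1:10, k_max = 12), class = "epifd_param_error")
  # n = 2 k values: estimate defined, standard errors NaN
  fit2 <- higuchi_fd(gen_fbm(0.5, 256, seed = 1)$x, k_values = c(2, 4))
  expect_true(is.finite(fit2$Df))
  expect_true(is.nan(fit2$S_Df) && is.nan(fit2$S_b))
})

test_that("fBm calibration: estimated Df tracks 2 - H", {
  for (H in c(0.2, 0.5, 0.8)) {
    dfs <- vapply(1:8, function(s) higuchi_fd(gen_fbm(H, 8192, seed = s)$x,
                                              k_max = 64)$Df, 0.0)
    expect_lt(abs(median(dfs) - (2 - H)), 0.1)
  }
})

test_that("Df stays in the theoretical band across signal classes", {
  set.seed(77)
  n <- 4096
  t <- seq_len(n) / 128
  signals <- list(
    ramp = seq_len(n),
    sine = sin(2 * pi * 1.2 * t),
    fbm = gen_fbm(0.5, n, seed = 3)$x,
    white = rnorm(n)
  )
  for (nm in names(signals)) {
    df <- higuchi_fd(signals[[nm]], k_max = 64)$Df
    expect_gte(df, 1 - 1e-9)
    expect_lte(df, 2.05)
  }
  expect_gte(higuchi_fd(signals$white, k_max = 64)$Df, 1.9)
})
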
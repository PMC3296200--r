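test_that("fGn has the closed-form lag-1 autocorrelation", {
  # H = 0.5: white noise, uncorrelated
  g <- gen_fgn(0.5, 8192, seed = 1)$x
  expect_lt(abs(cor(g[-1], g[-length(g)])), 0.05)
  expect_equal(sd(g), 1, tolerance = 0.1)
  # H = 0.8: rho(1) = (2^(2H) - 2)/2, averaged over seeds
  rho_theory <- (2^1.6 - 2) / 2
  rhos <- vapply(1:20, function(s) {
    x <- gen_fgn(0.8, 8192, seed = s)$x
    cor(x[-1], x[-length(x)])
  }, 0.0)
  expect_lt(abs(mean(rhos) - rho_theory), 0.05)
})

test_that("generators are pure functions of (params, seed)", {
  expect_identical(gen_fgn(0.3, 1024, seed = 9), gen_fgn(0.3, 1024, seed = 9))
  expect_false(identical(gen_fgn(0.3, 1024, seed = 9)$x,
                         gen_fgn(0.3, 1024, seed = 10)$x))
  a <- gen_seizure_recording(duration_s = 64, onset_s = 40, n_channels = 2,
                            seed = 4)
  b <- gen_seizure_recording(duration_s = 64, onset_s = 40, n_channels = 2,
                            seed = 4)
  expect_identical(a, b)
})

test_that("generator parameter validation", {
  expect_error(gen_fgn(1.5, 1024), class = "epifd_param_error")
  expect_error(gen_fgn(0.5, 1000), class = "epifd_param_error")
  expect_error(gen_mixture(c("laplace", "laplace"), A = diag(2), n = 100)$x,
               NA)
  expect_error(gen_mixture("laplace", A = diag(2), n = 100),
               class = "epifd_param_error")
  expect_error(gen_seizure_recording(duration_s = 10, onset_s = 5),
               class = "epifd_param_error")
  expect_error(gen_seizure_recording(duration_s = 100, onset_s = 200),
               class = "epifd_param_error")
})

test_that("identity mixing returns the sources themselves", {
  g <- gen_mixture(c("laplace", "sine"), A = diag(2), n = 2000, seed = 2)
  expect_equal(unname(g$recording$data), unname(g$truth$S))
})

test_that("mixture channel covariance matches A %*% t(A) within 5%", {
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  g <- gen_mixture(c("laplace", "laplace"), A, n = 20000, seed = 5)
  C <- tcrossprod(center_rows(g$recording$data)) / (20000 - 1)
  expect_equal(unname(C), A %*% t(A), tolerance = 0.05)
})

test_that("0 dB SNR gives equal signal and noise power within 5%", {
  A <- diag(2)
  clean <- gen_mixture(c("laplace", "laplace"), A, n = 50000, seed = 7)
  noisy <- gen_mixture(c("laplace", "laplace"), A, n = 50000,
                       noise_snr_db = 0, seed = 7)
  p_sig <- mean(clean$recording$data^2)
  p_noise <- mean((noisy$recording$data - clean$recording$data)^2)
  expect_equal(p_noise / p_sig, 1, tolerance = 0.05)
})

test_that("seizure truth stores the exact onset sample", {
  g <- gen_seizure_recording(fs = 128, duration_s = 600, onset_s = 300,
                             n_channels = 2, seed = 1)
  expect_equal(g$truth$onset_sample, 38400)
  expect_equal(g$truth$source_index, 1L)
  expect_equal(dim(g$recording$data), c(2L, 600L * 128L))
})

test_that("latent epileptic source: preictal windows out-FD ictal windows", {
  g <- gen_seizure_recording(fs = 128, duration_s = 480, onset_s = 240,
                             n_channels = 2, seed = 3)
  tc <- fd_timecourse(g$truth$S[1, ], fs = 128)
  pre <- tc$fd[1, tc$times < 240 - g$truth$params$transition_s]
  ict <- tc$fd[1, tc$times >= 240 + 8 & tc$times <= 240 + 8]  # fully in plateau
  expect_true(length(pre) > 0 && length(ict) > 0)
  expect_true(all(outer(pre, ict, ">")))
  # background sources stay below the preictal epileptic level
  bg <- fd_timecourse(g$truth$S[2, ], fs = 128)
  expect_lt(mean(bg$fd[1, ]), min(pre))
})
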
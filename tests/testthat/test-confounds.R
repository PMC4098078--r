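test_that("temporal derivative is the backward difference with leading zero", {
  expect_equal(temporal_derivative(rep(3, 10)), rep(0, 10))
  ramp <- 0.7 * (0:9)
  expect_equal(temporal_derivative(ramp), c(0, rep(0.7, 9)))
  withr::with_seed(1, x <- rnorm(50))
  oracle <- c(0, x[-1] - x[-length(x)])  # element-by-element subtraction
  expect_equal(temporal_derivative(x), oracle)
  expect_error(temporal_derivative(1), "length >= 2")
})

test_that("nuisance design has 30 columns in the documented order", {
  withr::with_seed(2, {
    motion <- matrix(rnorm(60), 10, 6)
    tissue <- matrix(rnorm(30), 10, 3)
  })
  design <- build_nuisance_matrix(motion, tissue)
  expect_s3_class(design, "rfc_nuisance_design")
  expect_equal(ncol(design$matrix), 30L)
  expect_equal(length(design$column_names), 30L)
  # motion, derivatives, tissue, then squares of those 15
  expect_equal(design$matrix[, 1:6], motion, ignore_attr = TRUE)
  expect_equal(design$matrix[, 7], temporal_derivative(motion[, 1]),
               ignore_attr = TRUE)
  expect_equal(design$matrix[, 13:15], tissue, ignore_attr = TRUE)
  expect_equal(design$matrix[, 16], motion[, 1]^2, ignore_attr = TRUE)
  expect_equal(design$matrix[, 28:30], tissue^2, ignore_attr = TRUE)

  zeros <- build_nuisance_matrix(matrix(0, 5, 6), matrix(0, 5, 3))
  expect_true(all(zeros$matrix == 0))
  expect_error(build_nuisance_matrix(matrix(0, 5, 6), matrix(0, 4, 3)),
               "same volumes")
  expect_error(build_nuisance_matrix(matrix(NA_real_, 5, 6), matrix(0, 5, 3)))
})

test_that("residualize matches the normal-equations oracle and is idempotent", {
  withr::with_seed(3, {
    x <- matrix(rnorm(200 * 5), 200, 5)
    y <- matrix(rnorm(200 * 3), 200, 3)
  })
  res <- residualize(y, x)
  oracle <- ols_residual_oracle(y, x)
  expect_lt(max(abs(res - oracle)), 1e-8)
  # orthogonal to every design column including the intercept
  xi <- cbind(1, x)
  expect_lt(max(abs(t(xi) %*% res)) / max(abs(y)), 1e-8)
  expect_lt(max(abs(residualize(res, x) - res)), 1e-8)
})

test_that("residualize removes design columns exactly and passes orthogonal series", {
  withr::with_seed(4, x <- matrix(rnorm(100 * 4), 100, 4))
  expect_lt(max(abs(residualize(x[, 2, drop = FALSE], x))), 1e-10)
  # zero-mean series orthogonal to the design survives unchanged
  withr::with_seed(5, y <- rnorm(100))
  y <- drop(ols_residual_oracle(matrix(y), x))
  expect_lt(max(abs(residualize(matrix(y), x) - y)), 1e-8)
})

test_that("rank-deficient designs fall back to pivoted least squares with warning", {
  withr::with_seed(6, x <- matrix(rnorm(50 * 2), 50, 2))
  xdup <- cbind(x, x[, 1])
  withr::with_seed(7, y <- matrix(rnorm(50)))
  expect_warning(res <- residualize(y, xdup), "rank deficient")
  expect_equal(res, residualize(y, x), ignore_attr = TRUE)
})

test_that("band-pass keeps 0.04 Hz and rejects out-of-band signals", {
  # passband at the study TR of 2 s
  tr <- 2; n <- 600; t <- (0:(n - 1)) * tr
  s_pass <- sin(2 * pi * 0.04 * t)
  out <- bandpass_filter(s_pass, tr_s = tr)
  gain <- fft_amplitude(out[50:(n - 50)], 0.04, tr) /
    fft_amplitude(s_pass[50:(n - 50)], 0.04, tr)
  expect_gte(gain, 0.9)
  # stopband at TR 1 s, where 0.2 Hz is below Nyquist
  tr1 <- 1; t1 <- (0:(n - 1)) * tr1
  s_stop <- sin(2 * pi * 0.2 * t1)
  out_stop <- bandpass_filter(s_stop, tr_s = tr1)
  gain_stop <- fft_amplitude(out_stop[50:(n - 50)], 0.2, tr1) /
    fft_amplitude(s_stop[50:(n - 50)], 0.2, tr1)
  expect_lte(gain_stop, 0.1)
  # DC is removed
  const <- bandpass_filter(rep(5, 400), tr_s = 2)
  expect_lt(max(abs(const)), 1e-6)
})

test_that("band-pass validates edges and segment length", {
  expect_error(bandpass_filter(matrix(rnorm(600), 600, 1), tr_s = 2, high_hz = 0.3),
               "Nyquist")
  expect_error(bandpass_filter(matrix(rnorm(8), 8, 1), tr_s = 2),
               "full continuous runs")
})
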
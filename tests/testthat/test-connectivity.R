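test_that("pearson_matrix matches the longhand covariance-formula oracle", {
  withr::with_seed(21, m <- matrix(rnorm(90 * 10), 90, 10))
  r <- pearson_matrix(m)
  # longhand: centered cross-products over sqrt of products of sums of squares
  mc <- sweep(m, 2, colMeans(m))
  num <- t(mc) %*% mc
  ss <- sqrt(diag(num))
  oracle <- num / (ss %o% ss)
  expect_lt(max(abs(r - oracle)), 1e-12)
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(1, 10), ignore_attr = TRUE)
})

test_that("pearson_matrix handles exact and degenerate cases", {
  x <- c(0.3, -1.2, 2.2, 0.4)
  expect_equal(pearson_matrix(cbind(x, x))[1, 2], 1)
  ortho <- cbind(a = c(1, 0, -1, 0), b = c(0, 1, 0, -1))
  expect_equal(pearson_matrix(ortho)[1, 2], 0)
  expect_error(pearson_matrix(cbind(a = x, b = rep(1, 4))), "b")
  # affine rescaling with positive slope leaves correlations unchanged
  withr::with_seed(22, m <- matrix(rnorm(60 * 4), 60, 4))
  m2 <- m; m2[, 2] <- 5 + 3 * m2[, 2]
  expect_equal(pearson_matrix(m), pearson_matrix(m2), tolerance = 1e-12)
})

test_that("fisher_z matches the closed form and its properties", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(abs(fisher_z(r)) >= abs(r)))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(inverse_fisher_z(fisher_z(0.73)), 0.73, tolerance = 1e-12)
  expect_error(fisher_z(1), "undefined")
})

test_that("connectivity matrices flatten into the canonical edge table", {
  withr::with_seed(23, {
    s1 <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
    s2 <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  z1 <- connectivity_matrix(s1)
  expect_true(is.na(z1[1, 1]))
  expect_equal(z1[1, 2], atanh(cor(s1[, 1], s1[, 2])))
  tbl <- cohort_edge_table(list(A = s1, B = s2))
  expect_equal(names(tbl), c("subject", "a--b", "a--c", "b--c"))
  expect_equal(tbl$`b--c`[2], atanh(cor(s2[, 2], s2[, 3])))
})

test_that("covariate adjustment matches the normal-equations oracle", {
  withr::with_seed(24, {
    n <- 30
    age <- rnorm(n, 25, 3)
    sex <- rbinom(n, 1, 0.5)
    y <- rnorm(n)
  })
  adj <- adjust_covariates(y, age, sex, keep_mean = FALSE)
  oracle <- drop(ols_residual_oracle(matrix(y), cbind(age, sex)))
  expect_lt(max(abs(adj - oracle)), 1e-10)
  # residual correlation with covariates vanishes
  adj_m <- adjust_covariates(y, age, sex)
  expect_lt(abs(cor(adj_m, age)), 1e-8)
  expect_lt(abs(cor(adj_m, sex)), 1e-8)
  expect_equal(mean(adj_m), mean(y), tolerance = 1e-10)
})

test_that("adjustment removes exact covariate dependence and keeps orthogonal signal", {
  withr::with_seed(25, {
    age <- rnorm(20, 25, 3); sex <- rbinom(20, 1, 0.5)
  })
  y_lin <- 2 + 0.5 * age
  adj <- adjust_covariates(y_lin, age, sex)
  expect_lt(max(abs(adj - mean(y_lin))), 1e-10)
  # a signal orthogonal to centered covariates is preserved up to its mean
  raw <- rnorm(20)
  ortho <- drop(ols_residual_oracle(matrix(raw), cbind(age, sex)))
  expect_equal(adjust_covariates(ortho, age, sex), ortho + mean(ortho),
               tolerance = 1e-8)
  expect_warning(adjust_covariates(raw, age, rep(1, 20)), "constant covariate")
})

test_that("adjust_edge_table aligns subjects through the cohort table", {
  cfg <- small_sim_config()
  cohort <- simulate_cohort(cfg)
  tbl <- cohort_edge_table(rest_series(cohort), cfg$seed_names)
  adj <- adjust_edge_table(tbl, cohort$cohort)
  expect_equal(dim(adj), dim(tbl))
  e <- names(tbl)[2]
  expect_equal(adj[[e]],
               adjust_covariates(tbl[[e]], cohort$cohort$age, cohort$cohort$sex))
  expect_error(adjust_edge_table(tbl, cohort$cohort[-1, ]), "missing")
})
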
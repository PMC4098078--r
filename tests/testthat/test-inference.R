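test_that("Cohen's d follows the pooled-SD longhand formula", {
  # longhand: means 2 and 1, variances 1 and 1, pooled SD 1
  expect_equal(cohens_d(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_equal(cohens_d(c(2, 4), c(2, 4)), 0)
  a <- c(0.5, 1.5, 2.5, 4.0); b <- c(1.1, 0.2, 3.3)
  sp <- sqrt((3 * var(a) + 2 * var(b)) / 5)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "Pooled SD")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("edge main effects: t statistics, CDF oracle, and degenerate edges", {
  withr::with_seed(41, {
    jitter <- rnorm(43, 0, 1e-3)
  })
  z <- cbind(zero = rep(0, 43), strong = 0.5 + jitter)
  expect_warning(res <- edge_main_effects(z), "zero-variance")
  expect_equal(res$t[res$edge == "zero"], 0)
  expect_false(res$fdr_main_effect[res$edge == "zero"])
  tt <- res$t[res$edge == "strong"]
  expect_gt(tt, 100)
  # p cross-checked against the t-distribution CDF
  expect_equal(res$p[res$edge == "strong"], 2 * pt(-abs(tt), df = 42),
               tolerance = 1e-12)
  expect_true(res$fdr_main_effect[res$edge == "strong"])
})

test_that("posterior matches exhaustive label enumeration for 3-vs-3 groups", {
  a <- c(2.1, 2.6, 3.0)
  b <- c(0.4, 1.0, 1.4)
  pooled <- c(a, b)
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(ix) {
    median(pooled[ix]) - median(pooled[-ix])
  })
  obs <- median(a) - median(b)
  exhaustive <- sum(stats < obs) / ncol(combos)  # observed direction (obs > 0)
  mc <- median_diff_perm_test(a, b, inference_config(n_permutations = 10000,
                                                     rng_seed = 3))
  expect_equal(mc$observed, obs)
  expect_lt(abs(mc$posterior - exhaustive), 0.02)
})

test_that("Monte-Carlo posteriors converge to the enumerated value", {
  a <- c(1.8, 2.4, 2.9); b <- c(0.9, 1.2, 2.0)
  pooled <- c(a, b)
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(ix) median(pooled[ix]) - median(pooled[-ix]))
  obs <- median(a) - median(b)
  exhaustive <- sum(stats < obs) / ncol(combos)
  errs <- vapply(c(200, 2000, 20000), function(B) {
    mc <- median_diff_perm_test(a, b, inference_config(n_permutations = B,
                                                       rng_seed = 11))
    abs(mc$posterior - exhaustive)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 0.01)
})

test_that("the permutation test is seeded, exchangeable, and direction-symmetric", {
  withr::with_seed(42, {
    pool <- rnorm(43)
  })
  a <- pool[1:20]; b <- pool[21:43]
  cfg <- inference_config(n_permutations = 2000, rng_seed = 5)
  r1 <- median_diff_perm_test(a, b, cfg)
  r2 <- median_diff_perm_test(a, b, cfg)
  expect_identical(r1, r2)
  # shuffled same-distribution groups hover near 0.5
  posts <- vapply(1:20, function(i) {
    withr::with_seed(i, p <- sample(pool))
    median_diff_perm_test(p[1:20], p[21:43],
                          inference_config(n_permutations = 500,
                                           rng_seed = 100 + i))$posterior
  }, numeric(1))
  expect_lt(abs(mean(posts) - 0.5), 0.1)
  # swapping groups negates the statistic and mirrors the posterior
  sw <- median_diff_perm_test(b, a, cfg)
  expect_equal(sw$observed, -r1$observed)
  expect_lt(abs(sw$posterior - (1 - r1$posterior)), 0.05)
  expect_warning(
    deg <- median_diff_perm_test(rep(1, 5), rep(1, 6),
                                 inference_config(n_permutations = 100)),
    "Degenerate")
  expect_equal(deg$posterior, 0.5)
})

test_that("effect-size gates require posterior, r, and d jointly", {
  stats <- tibble::tibble(
    edge = c("pass", "small_d", "small_r", "weak_posterior"),
    posterior = c(0.995, 0.99, 0.99, 0.90),
    r_expert = c(0.30, 0.30, 0.05, 0.30),
    r_nonexpert = c(0.10, 0.10, -0.05, 0.10),
    d = c(1.00, 0.50, 1.20, 1.00))
  gated <- gate_edges(stats, inference_config())
  expect_equal(gated$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(gated$flagged ==
                    (gated$posterior_pass & gated$r_gate_pass & gated$d_gate_pass)))
})

test_that("Spearman edge-behavior correlation matches a manual rank oracle", {
  cfg <- inference_config()
  up <- tibble::tibble(subject = letters[1:6], e = c(1, 2, 4, 8, 16, 32))
  expect_equal(spearman_edge_behavior(up, c(10, 20, 30, 40, 50, 60), cfg)$rho, 1)
  expect_equal(spearman_edge_behavior(up, c(60, 50, 40, 30, 20, 10), cfg)$rho, -1)
  # ties handled by average ranks: oracle built by hand
  edge_vals <- c(1.0, 1.0, 2.0, 3.0, 3.0, 4.0)
  score <- c(2, 1, 1, 3, 5, 4)
  hand_rank_edge <- c(1.5, 1.5, 3, 4.5, 4.5, 6)
  hand_rank_score <- c(3, 1.5, 1.5, 4, 6, 5)
  oracle <- cor(hand_rank_edge, hand_rank_score)
  tied <- tibble::tibble(subject = letters[1:6], e = edge_vals)
  got <- spearman_edge_behavior(tied, score, cfg)
  expect_lt(abs(got$rho - oracle), 1e-12)
  # t-approximation p-value
  n <- 6; tstat <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  expect_error(spearman_edge_behavior(up, rep(1, 6), cfg), "constant")
})

test_that("the gated group test returns a tidy, coherent edge table", {
  cfg <- small_sim_config(rng_seed = 7)
  cohort <- simulate_cohort(cfg)
  tbl <- adjust_edge_table(cohort_edge_table(rest_series(cohort), cfg$seed_names),
                           cohort$cohort)
  fit <- rfc_group_test(tbl, cohort$cohort,
                        inference_config(n_permutations = 200, rng_seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 45L)
  expect_true(all(td$posterior > 0 & td$posterior < 1))
  expect_true(all(td$flagged == (td$posterior_pass & td$r_gate_pass & td$d_gate_pass)))
  expect_equal(td$r_expert, tanh(td$median_expert))
  gl <- glance(fit)
  expect_equal(gl$n_expert, 5L)
  expect_equal(gl$n_edges, 45L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
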
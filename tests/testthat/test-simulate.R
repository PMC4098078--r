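test_that("group covariance is base plus planted deltas, PD preserved", {
  base <- diag(3)
  dimnames(base) <- list(letters[1:3], letters[1:3])
  expect_equal(build_group_covariance(base, NULL, "expert"), base)

  eff <- tibble::tibble(seed_a = "a", seed_b = "b", group = "expert", delta_r = 0.5)
  out <- build_group_covariance(base, eff, "expert")
  expect_equal(out["a", "b"], 0.5)
  expect_equal(out["b", "a"], 0.5)
  expect_gt(min(eigen(out, symmetric = TRUE)$values), 0)
  # effects for another group leave the matrix untouched
  expect_equal(build_group_covariance(base, eff, "nonexpert"), base)
  eff_bad <- tibble::tibble(seed_a = "a", seed_b = "b", group = "expert", delta_r = 0.999)
  base2 <- base; base2["a", "b"] <- base2["b", "a"] <- 0.5
  expect_error(build_group_covariance(base2, eff_bad, "expert"), "outside")
})

test_that("non-PD perturbations are repaired by eigenvalue clipping", {
  base <- matrix(0.0, 3, 3); diag(base) <- 1
  dimnames(base) <- list(letters[1:3], letters[1:3])
  # r(a,b)=0.9, r(a,c)=0.9, r(b,c)=-0.9 is not PD
  eff <- tibble::tibble(seed_a = c("a", "a", "b"), seed_b = c("b", "c", "c"),
                        group = "g", delta_r = c(0.9, 0.9, -0.9))
  expect_message(out <- build_group_covariance(base, eff, "g"), "Repairing")
  # independent eigendecomposition oracle on the repaired matrix; the
  # diagonal renormalization after clipping can shrink the floor slightly
  ev <- eigen(out, symmetric = TRUE)$values
  expect_gte(min(ev), 1e-4 * 0.5)
  expect_equal(diag(out), rep(1, 3), ignore_attr = TRUE)
  expect_equal(out, t(out))
})

test_that("simulated subjects are bit-identical under a fixed seed", {
  cfg <- small_sim_config()
  a <- simulate_subject(cfg, "expert", 77)
  b <- simulate_subject(cfg, "expert", 77)
  expect_identical(a, b)
  c <- simulate_subject(cfg, "expert", 78)
  expect_false(identical(a$rest_series, c$rest_series))
})

test_that("null covariance yields null-scale sample correlations at 90 volumes", {
  cfg <- simulation_config(n_expert = 2, n_nonexpert = 2, seed_names = c("s1", "s2"),
                           base_correlation = diag(2), planted_effects = NULL,
                           behavior_couplings = NULL, mode = "rest_only",
                           rng_seed = 1)
  rs <- vapply(1:150, function(i) {
    s <- simulate_subject(cfg, "expert", i)$rest_series
    cor(s[, 1], s[, 2])
  }, numeric(1))
  # E|r| under the null at n=90 is about sqrt(2/(pi*(n-1))) ~ 0.085
  expect_lt(abs(mean(rs)), 0.03)
  expect_lt(mean(abs(rs)), 0.085 + 0.03)
  expect_gt(mean(abs(rs)), 0.085 - 0.03)
})

test_that("a planted r = 0.9 is recovered to within 0.05 on average", {
  base <- diag(2); dimnames(base) <- list(c("s1", "s2"), c("s1", "s2"))
  eff <- tibble::tibble(seed_a = "s1", seed_b = "s2", group = "expert", delta_r = 0.9)
  cfg <- simulation_config(n_expert = 2, n_nonexpert = 2, seed_names = c("s1", "s2"),
                           base_correlation = base, planted_effects = eff,
                           behavior_couplings = NULL, mode = "rest_only",
                           rng_seed = 1)
  rs <- vapply(1:120, function(i) {
    s <- simulate_subject(cfg, "expert", i)$rest_series
    cor(s[, 1], s[, 2])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.05)
})

test_that("empirical correlations converge to the generating covariance", {
  cfg <- simulation_config(mode = "rest_only")
  sigma <- build_group_covariance(cfg$base_correlation, cfg$planted_effects, "expert")
  long <- with(list(), {
    layout <- acquisition_layout(
      runs = 1,
      blocks_per_run = tibble::tibble(condition = "rest", duration_volumes = 6000))
    rcfg <- rest_selection_config(drop_initial_per_rest = 0,
                                  retained_per_rest = 6000,
                                  end_rest_volumes = 0,
                                  discard_run_initial_volumes = 0)
    cfg_long <- simulation_config(layout = layout, rest_cfg = rcfg,
                                  mode = "rest_only", rng_seed = 5)
    simulate_subject(cfg_long, "expert", 42)$rest_series
  })
  expect_gte(nrow(long), 5000)
  expect_lt(max(abs(cor(long) - sigma)), 0.05)
})

test_that("voxel bundles are rank-1 dominated with positively coupled voxels", {
  cfg <- small_sim_config(voxels_per_seed = 12)
  sub <- simulate_subject(cfg, "expert", 9)
  vox <- sub$rest_series[, grep("^L44\\.v", colnames(sub$rest_series))]
  expect_equal(ncol(vox), 12L)
  cm <- cor(vox)
  expect_gt(mean(cm[upper.tri(cm)]), 0)
  sv <- svd(scale(vox, scale = FALSE))$d
  expect_gt(sv[1]^2 / sum(sv^2), 0.4)  # dominant first component
})

test_that("cohorts are reproducible and carry the study demographics", {
  cfg <- small_sim_config(rng_seed = 404)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  full <- simulate_cohort(simulation_config(mode = "rest_only", rng_seed = 1))
  expect_equal(sum(full$cohort$group == "expert"), 20)
  expect_equal(sum(full$cohort$group == "nonexpert"), 23)
  expect_equal(sum(full$cohort$sex[full$cohort$group == "expert"] == 0), 8)
  expect_equal(sum(full$cohort$sex[full$cohort$group == "nonexpert"] == 0), 11)
  expect_true(all(c("vci", "cr", "pi_score") %in% names(full$cohort)))
})

test_that("uncoupled behavior scores are independent of edge values", {
  cohort <- tibble::tibble(subject = sprintf("s%03d", 1:600),
                           group = rep(c("expert", "nonexpert"), 300))
  beh <- simulate_behavior(cohort, rng_seed = 8)
  withr::with_seed(9, fake_edge <- rnorm(600))
  expect_lt(abs(cor(beh$vci, fake_edge, method = "spearman")), 0.1)
})

test_that("a coupled score hits its target Spearman correlation on average", {
  couple <- tibble::tibble(seed_a = "L44", seed_b = "L_TP", score = "cr",
                           group_scope = "expert", target_rho = -0.62)
  rhos <- vapply(1:200, function(i) {
    cohort <- tibble::tibble(subject = sprintf("s%02d", 1:20), group = "expert")
    ev <- withr::with_seed(1000 + i,
      tibble::tibble(subject = cohort$subject, `L44--L_TP` = rnorm(20)))
    beh <- simulate_behavior(cohort, ev, couple, rng_seed = 2000 + i)
    cor(beh$cr, ev$`L44--L_TP`, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.62)), 0.1)
})

test_that("expert VCI replicates center on the configured mean", {
  means <- vapply(1:200, function(i) {
    cohort <- tibble::tibble(subject = sprintf("s%02d", 1:20), group = "expert")
    mean(simulate_behavior(cohort, rng_seed = i)$vci)
  }, numeric(1))
  expect_lt(abs(mean(means) - 116.5), 1)
})

test_that("coupling validation rejects duplicates and unsupported targets", {
  dup <- tibble::tibble(seed_a = c("a", "b"), seed_b = c("b", "c"),
                        score = "cr", group_scope = "expert",
                        target_rho = c(0.3, 0.4))
  cohort <- tibble::tibble(subject = "s1", group = "expert")
  expect_error(simulate_behavior(cohort, NULL, dup), "Inconsistent couplings")
  pi_c <- dup[1, ]; pi_c$score <- "pi"
  expect_error(simulate_behavior(cohort, NULL, pi_c), "vci.*cr|cr.*vci")
})

test_that("delta_r calibration reflects the Fisher-Z sampling spread", {
  d <- calibrate_delta_r(0, 1, n_volumes = 90)
  expect_equal(d, tanh(1 / sqrt(87)), tolerance = 1e-12)
  # band-limited series carry fewer effective samples -> larger delta
  d_band <- calibrate_delta_r(0, 1, n_volumes = 90, band = c(0.01, 0.08), tr_s = 2)
  expect_gt(d_band, d)
  expect_equal(d_band, tanh(1 / sqrt(90 * 0.07 / 0.25 - 3)), tolerance = 1e-12)
})
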
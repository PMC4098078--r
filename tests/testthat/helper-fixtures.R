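# shared fixtures: small layouts and configs used across test files

toy_layout <- function() {
  acquisition_layout(
    runs = 1,
    blocks_per_run = tibble::tibble(
      condition = c("rest", "task", "rest", "task", "end_rest"),
      duration_volumes = c(4, 5, 4, 5, 2)),
    tr_s = 2)
}

toy_rest_cfg <- function() {
  rest_selection_config(drop_initial_per_rest = 1, retained_per_rest = 3,
                        end_rest_volumes = 2, discard_run_initial_volumes = 0)
}

# small, fast cohort for unit tests (not the study-scale defaults)
small_sim_config <- function(..., rng_seed = 101) {
  simulation_config(n_expert = 5, n_nonexpert = 6, mode = "rest_only",
                    planted_effects = NULL, behavior_couplings = NULL,
                    rng_seed = rng_seed, ...)
}

# independent normal-equations residual oracle
ols_residual_oracle <- function(y, x) {
  x <- cbind(1, x)
  y - x %*% solve(t(x) %*% x, t(x) %*% y)
}

# FFT amplitude at a single frequency (spectral oracle for filter gain)
fft_amplitude <- function(x, freq_hz, tr_s) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  k <- which.min(abs(f - freq_hz))
  2 * Mod(stats::fft(x))[k] / n
}
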
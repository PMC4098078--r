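#' Replicate-cohort validation study
#'
#' Simulates many independent cohorts under one configuration, runs the
#' full edge analysis (connectivity, age/sex adjustment, gated group test)
#' on each, and tallies per-edge flag rates, mean Cohen's d, and —
#' optionally — the recovery of a planted behavior--connectivity coupling.
#' This is the package's calibration/power harness: with no planted
#' effects it measures the false-flag rate of the full gate; with planted
#' effects it measures recovery power.
#'
#' @param n_cohorts Number of independent cohorts.
#' @param config An [simulation_config()]; its `rng_seed` is re-derived per
#'   cohort from `rng_seed` below. Rest-only mode is recommended here for
#'   speed.
#' @param inference_cfg An [inference_config()] (use a reduced
#'   `n_permutations`, e.g. 1000, for large replicate counts).
#' @param rng_seed Master seed for the replicate stream.
#' @param behavior_edge Optional edge label `"A--B"` whose Spearman
#'   correlation with `behavior_score` is recorded per cohort.
#' @param behavior_score Score column for the behavior recovery (default
#'   `"cr"`).
#' @param behavior_scope `"expert"`, `"nonexpert"` or `"all"`.
#' @return A list: `edges` (tibble: edge, flag_rate, mean_d, mean_median_diff),
#'   `behavior` (tibble per cohort: rho, flagged; `NULL` unless
#'   `behavior_edge` given), `n_cohorts`.
#' @export
replicate_study <- function(n_cohorts, config = simulation_config(mode = "rest_only"),
                            inference_cfg = inference_config(n_permutations = 1000),
                            rng_seed = 1L,
                            behavior_edge = NULL,
                            behavior_score = "cr",
                            behavior_scope = "expert") {
  n_cohorts <- check_count(n_cohorts, "n_cohorts", lower = 1L)
  stopifnot(inherits(config, "rfc_sim_config"))
  flags <- NULL; dsum <- NULL; diffsum <- NULL
  behavior <- if (!is.null(behavior_edge)) {
    tibble::tibble(cohort = integer(0), rho = numeric(0), flagged = logical(0))
  }
  for (i in seq_len(n_cohorts)) {
    cfg_i <- config
    cfg_i$rng_seed <- as.integer(substream_seed(rng_seed, i))
    icfg_i <- inference_cfg
    icfg_i$rng_seed <- as.integer(substream_seed(rng_seed, 500000L + i))
    cohort <- simulate_cohort(cfg_i)
    series <- if (cohort$mode == "full") preprocess_cohort(cohort)
              else rest_series(cohort)
    if (cfg_i$voxels_per_seed > 1L) {
      series <- purrr::map(series, reduce_seed_voxels, seed_names = cfg_i$seed_names)
    }
    edge_tbl <- cohort_edge_table(series, cfg_i$seed_names)
    adjusted <- adjust_edge_table(edge_tbl, cohort$cohort)
    fit <- rfc_group_test(adjusted, cohort$cohort, icfg_i)
    if (is.null(flags)) {
      flags <- stats::setNames(numeric(nrow(fit$edges)), fit$edges$edge)
      dsum <- flags; diffsum <- flags
    }
    flags <- flags + fit$edges$flagged
    dsum <- dsum + fit$edges$d
    diffsum <- diffsum + fit$edges$median_diff
    if (!is.null(behavior_edge)) {
      keep <- if (behavior_scope == "all") rep(TRUE, nrow(cohort$cohort))
              else cohort$cohort$group == behavior_scope
      score_adj <- adjust_covariates(cohort$cohort[[behavior_score]],
                                     cohort$cohort$age, cohort$cohort$sex)
      res <- spearman_edge_behavior(
        adjusted[keep, c("subject", behavior_edge)], score_adj[keep], icfg_i)
      behavior <- dplyr::bind_rows(behavior, tibble::tibble(
        cohort = i, rho = res$rho[1], flagged = res$flagged[1]))
    }
  }
  list(
    edges = tibble::tibble(
      edge = names(flags),
      flag_rate = as.numeric(flags) / n_cohorts,
      mean_d = as.numeric(dsum) / n_cohorts,
      mean_median_diff = as.numeric(diffsum) / n_cohorts),
    behavior = behavior,
    n_cohorts = n_cohorts)
}

#' Null-calibration convenience configuration
#'
#' The default cohort with all planted connectivity effects and behavior
#' couplings removed, in rest-only mode — the null condition for
#' false-flag-rate calibration.
#'
#' @param ... Passed on to [simulation_config()].
#' @return An `rfc_sim_config`.
#' @export
null_simulation_config <- function(...) {
  simulation_config(planted_effects = NULL, behavior_couplings = NULL,
                    mode = "rest_only", ...)
}
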
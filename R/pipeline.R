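#' Preprocess one subject's raw runs
#'
#' Per run: discard the initial equilibration volumes, build the
#' 30-regressor nuisance design from the confound table, remove its variance
#' by OLS, band-pass filter the residuals (zero-phase, full continuous run),
#' then extract the retained rest volumes. Runs are concatenated into one
#' retained series per subject. In voxel mode, each seed's voxels are then
#' reduced to the first eigenvariate.
#'
#' @param runs List of raw volumes x channels matrices (one per run,
#'   including equilibration volumes).
#' @param confounds List of matching volumes x 9 confound matrices/tibbles
#'   (canonical columns: `trans_*`, `rot_*`, `tissue_*`).
#' @param layout The [acquisition_layout()].
#' @param rest_cfg A [rest_selection_config()].
#' @param band Passband in Hz (default `c(0.01, 0.08)`).
#' @param seed_names Seed labels; voxel columns `<seed>.v<k>` are collapsed
#'   per seed via [first_eigenvariate()].
#' @return Retained volumes x seeds matrix.
#' @export
preprocess_subject <- function(runs, confounds, layout,
                               rest_cfg = rest_selection_config(),
                               band = c(0.01, 0.08),
                               seed_names = NULL) {
  if (length(runs) != layout$runs || length(confounds) != length(runs)) {
    stop_restfc("`runs` and `confounds` must both have one element per run.")
  }
  sel <- select_rest_volumes(layout, rest_cfg)
  discard <- rest_cfg$discard_run_initial_volumes
  retained <- purrr::map(seq_along(runs), function(r) {
    y <- as.matrix(runs[[r]])
    conf <- as.matrix(confounds[[r]])[, canonical_confound_cols, drop = FALSE]
    if (nrow(y) != nrow(conf)) {
      stop_restfc("Run series and confound table differ in volume count.")
    }
    if (nrow(y) < discard + run_length(layout)) {
      stop_restfc("Run shorter than layout plus discarded volumes.")
    }
    keep <- (discard + 1L):nrow(y)
    y <- y[keep, , drop = FALSE]
    conf <- conf[keep, , drop = FALSE]
    design <- build_nuisance_matrix(conf[, 1:6, drop = FALSE],
                                    conf[, 7:9, drop = FALSE])
    resid <- residualize(y, design)
    filtered <- bandpass_filter(resid, tr_s = layout$tr_s,
                                low_hz = band[1], high_hz = band[2])
    filtered[sel$per_run[[r]] + 1L, , drop = FALSE]
  })
  out <- do.call(rbind, retained)
  if (!is.null(seed_names)) out <- reduce_seed_voxels(out, seed_names)
  out
}

# collapse voxel columns "<seed>.v<k>" to one eigenvariate column per seed;
# plain ROI columns pass through (standardized, a no-op for correlations)
reduce_seed_voxels <- function(series, seed_names) {
  cols <- colnames(series)
  if (is.null(cols)) stop_restfc("Series must have column names for seed reduction.")
  out <- vapply(seed_names, function(s) {
    vox <- grep(paste0("^", s, "\\.v[0-9]+$"), cols)
    if (!length(vox)) vox <- which(cols == s)
    if (!length(vox)) stop_restfc(sprintf("No columns found for seed '%s'.", s))
    first_eigenvariate(series[, vox, drop = FALSE], seed_name = s)
  }, numeric(nrow(series)))
  colnames(out) <- seed_names
  out
}

#' Preprocess a simulated full-mode cohort
#'
#' Applies [preprocess_subject()] to every subject of a full-mode
#' [simulate_cohort()] result.
#'
#' @param cohort An `rfc_cohort` with `mode = "full"`.
#' @param band Passband in Hz.
#' @return Named list of retained volumes x seeds matrices.
#' @export
preprocess_cohort <- function(cohort, band = c(0.01, 0.08)) {
  stopifnot(inherits(cohort, "rfc_cohort"))
  if (cohort$mode != "full") {
    stop_restfc("`preprocess_cohort()` applies to full-mode cohorts; use rest_series().")
  }
  cfg <- cohort$config
  purrr::map(cohort$series, function(sub) {
    preprocess_subject(sub$runs, sub$confounds, cfg$layout,
                       rest_cfg = cfg$rest_cfg, band = band,
                       seed_names = cfg$seed_names)
  })
}

#' Run the full resting-state connectivity analysis
#'
#' End-to-end orchestration: simulate (or accept) a cohort, preprocess raw
#' runs (full mode), compute per-subject Fisher-Z edge values, partial age
#' and sex out of edges and behavioral scores, run the gated group
#' difference test, and rank-correlate edges with the behavioral scores
#' across all subjects and within the expert group. When `out_dir` is given,
#' writes `edges.tsv`, `behavior_corr.tsv`, `summary.json` and `run.log`.
#'
#' @param sim_config An [simulation_config()] (simulate mode), or an
#'   already-simulated `rfc_cohort`.
#' @param inference_cfg An [inference_config()].
#' @param band Passband in Hz for full-mode preprocessing.
#' @param scores Behavioral scores to correlate (default vci, cr,
#'   pi_score).
#' @param out_dir Optional output directory.
#' @return A list of class `rfc_run`: `cohort`, `edge_table` (raw),
#'   `adjusted_edges`, `edge_test` (an `rfc_edge_test`), `behavior`
#'   (correlation tibble with a `scope` column), `config`, `paths`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         inference_cfg = inference_config(),
                         band = c(0.01, 0.08),
                         scores = c("vci", "cr", "pi_score"),
                         out_dir = NULL) {
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    invisible(line)
  }

  cohort <- if (inherits(sim_config, "rfc_cohort")) sim_config
            else simulate_cohort(sim_config)
  cfg <- cohort$config
  log_msg("cohort: %d subjects, mode %s, rng_seed %d",
          nrow(cohort$cohort), cohort$mode, cfg$rng_seed)

  series <- if (cohort$mode == "full") {
    log_msg("preprocessing full runs (confound removal + band-pass %g-%g Hz)",
            band[1], band[2])
    preprocess_cohort(cohort, band = band)
  } else {
    rest_series(cohort)
  }
  if (cohort$mode == "rest_only" && cfg$voxels_per_seed > 1L) {
    series <- purrr::map(series, reduce_seed_voxels, seed_names = cfg$seed_names)
  }

  edge_tbl <- cohort_edge_table(series, cfg$seed_names)
  adjusted <- adjust_edge_table(edge_tbl, cohort$cohort)
  log_msg("computed %d edges for %d subjects", ncol(edge_tbl) - 1L, nrow(edge_tbl))

  fit <- rfc_group_test(adjusted, cohort$cohort, inference_cfg)
  log_msg("group test: %d flagged edge(s) of %d", sum(fit$edges$flagged),
          nrow(fit$edges))

  scope_rows <- list(all = rep(TRUE, nrow(cohort$cohort)),
                     expert = cohort$cohort$group == "expert")
  behavior <- purrr::imap(scope_rows, function(keep, scope) {
    purrr::map(intersect(scores, names(cohort$cohort)), function(sc) {
      vals <- adjust_covariates(cohort$cohort[[sc]], cohort$cohort$age,
                                cohort$cohort$sex)
      res <- spearman_edge_behavior(adjusted[keep, , drop = FALSE],
                                    vals[keep], inference_cfg)
      dplyr::mutate(res, scope = scope, score = sc, .before = 1L)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  log_msg("behavior correlations: %d flagged edge-score pair(s)",
          sum(behavior$flagged))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      edges = file.path(out_dir, "edges.tsv"),
      behavior = file.path(out_dir, "behavior_corr.tsv"),
      summary = file.path(out_dir, "summary.json"),
      log = file.path(out_dir, "run.log"))
    readr::write_tsv(fit$edges, paths$edges)
    readr::write_tsv(behavior, paths$behavior)
    summary <- list(
      n_expert = fit$n_expert, n_nonexpert = fit$n_nonexpert,
      mode = cohort$mode,
      seeds = cfg$seed_names,
      rng_seed = cfg$rng_seed,
      inference = unclass(inference_cfg),
      band_hz = band,
      n_edges = nrow(fit$edges),
      flagged_edges = fit$edges$edge[fit$edges$flagged],
      flagged_behavior = behavior[behavior$flagged,
                                  c("scope", "score", "edge", "rho", "p")])
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(log_lines, paths$log)
  }

  structure(
    list(cohort = cohort, edge_table = edge_tbl, adjusted_edges = adjusted,
         edge_test = fit, behavior = behavior,
         config = list(inference = inference_cfg, band = band), paths = paths),
    class = "rfc_run"
  )
}

#' @export
print.rfc_run <- function(x, ...) {
  print(x$edge_test)
  flagged <- x$behavior[x$behavior$flagged, ]
  cat(sprintf("  flagged behavior correlations: %d\n", nrow(flagged)))
  invisible(x)
}

#' Read per-subject ROI series TSVs
#'
#' Loads pre-extracted retained ROI x time series (one TSV per subject,
#' columns = seed names) for real-data mode.
#'
#' @param files Named character vector of TSV paths (names = subject ids).
#' @return Named list of volumes x seeds matrices.
#' @export
read_roi_series <- function(files) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop_restfc("`files` must be a named vector (names = subject ids).")
  }
  purrr::map(files, function(f) {
    if (!file.exists(f)) stop_restfc(sprintf("ROI series file not found: %s", f))
    as.matrix(readr::read_tsv(f, show_col_types = FALSE))
  })
}

#' Read a cohort table
#'
#' @param path CSV (or TSV) file with at least `subject`, `group`, `age`,
#'   `sex` columns; behavioral columns are kept as-is.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_restfc(sprintf("Cohort file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  cohort <- reader(path, show_col_types = FALSE)
  needed <- c("subject", "group", "age", "sex")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop_restfc(paste0("Cohort table missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(cohort)
}

#' Write a simulated cohort to disk
#'
#' Writes per-subject ROI series TSVs (retained volumes for rest-only
#' cohorts, raw runs otherwise), per-run confound TSVs (full mode), the
#' cohort CSV, and a layout JSON.
#'
#' @param cohort An `rfc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rfc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$cohort, file.path(dir, "cohort.csv"))
  for (id in names(cohort$series)) {
    sub <- cohort$series[[id]]
    if (cohort$mode == "rest_only") {
      readr::write_tsv(tibble::as_tibble(sub$rest_series),
                       file.path(dir, paste0(id, "_rest.tsv")))
    } else {
      for (r in seq_along(sub$runs)) {
        readr::write_tsv(tibble::as_tibble(sub$runs[[r]]),
                         file.path(dir, sprintf("%s_run-%d_bold.tsv", id, r)))
        readr::write_tsv(tibble::as_tibble(sub$confounds[[r]]),
                         file.path(dir, sprintf("%s_run-%d_confounds.tsv", id, r)))
      }
    }
  }
  layout <- cohort$layout
  jsonlite::write_json(
    list(runs = layout$runs, tr_s = layout$tr_s, blocks = layout$blocks),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
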
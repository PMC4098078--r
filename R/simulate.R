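#' Default baseline correlation structure of the seed network
#'
#' Baseline (non-expert) seed-to-seed correlation matrix used by the
#' synthetic cohort generator. Seed pairs reported as robustly coupled at
#' rest in the emulated study (bilateral IPS, bilateral area 44, bilateral
#' caudate, IPS with ipsilateral area 44, left IPS with right area 44, left
#' hippocampus with left temporal pole, left area 44 with MCC) receive a
#' moderate correlation; all remaining pairs a weak positive background.
#' The magnitudes are free parameters of the generator (the study reports
#' only group-level statistics on an ambiguous scale); see the vignette.
#'
#' @param seed_names Seed order (default: [seed_set()] names).
#' @param connected_r Correlation for the coupled pairs (default 0.35).
#' @param background_r Correlation for all other pairs (default 0.08).
#' @return Symmetric unit-diagonal correlation matrix with dimnames.
#' @export
default_base_correlation <- function(seed_names = seed_set()$name,
                                     connected_r = 0.35,
                                     background_r = 0.08) {
  k <- length(seed_names)
  base <- matrix(background_r, k, k, dimnames = list(seed_names, seed_names))
  diag(base) <- 1
  coupled <- list(
    c("L_IPS", "R_IPS"), c("L44", "R44"), c("L_CAUD", "R_CAUD"),
    c("R_IPS", "R44"), c("L_IPS", "L44"), c("L_IPS", "R44"),
    c("L_HIP", "L_TP"), c("L44", "MCC"))
  for (pair in coupled) {
    if (all(pair %in% seed_names)) {
      base[pair[1], pair[2]] <- base[pair[2], pair[1]] <- connected_r
    }
  }
  base
}

#' Calibrate a correlation-scale perturbation to a target Cohen's d
#'
#' Group differences are planted on the correlation scale but the analysis
#' measures them as Cohen's d on subject-level Fisher-Z values, whose
#' between-subject spread (subjects sharing one true correlation) is the
#' Fisher-Z sampling SD, approximately `1/sqrt(n_eff - 3)`. Band-pass
#' filtering reduces the effective number of independent volumes: for ideal
#' band-limited noise the variance inflation equals the inverse of the
#' retained bandwidth fraction, so `n_eff = n_volumes * (high - low) /
#' nyquist` when a filter band is supplied.
#'
#' @param base_r Baseline correlation at the edge.
#' @param target_d Signed target Cohen's d of the group difference.
#' @param n_volumes Retained rest volumes per subject (default 90).
#' @param band Optional numeric length-2 filter band in Hz; reduces the
#'   effective sample size as above.
#' @param tr_s Repetition time, used with `band` (default 2).
#' @return The `delta_r` to add to `base_r` for the affected group.
#' @export
calibrate_delta_r <- function(base_r, target_d, n_volumes = 90,
                              band = NULL, tr_s = 2) {
  check_number(base_r, "base_r", lower = -1 + 1e-9, upper = 1 - 1e-9)
  check_number(target_d, "target_d")
  n_eff <- n_volumes
  if (!is.null(band)) {
    nyquist <- 1 / (2 * tr_s)
    n_eff <- n_volumes * (band[2] - band[1]) / nyquist
  }
  if (n_eff <= 4) stop_restfc("Effective sample size too small to calibrate.")
  delta_z <- target_d / sqrt(n_eff - 3)
  tanh(atanh(base_r) + delta_z) - base_r
}

#' Planted expert-group connectivity pattern
#'
#' The qualitative expert/non-expert difference pattern the generator plants
#' by default: increased right IPS -- right caudate coupling (target d =
#' +1.00) and decreased interhemispheric area 44 coupling (target d =
#' -1.08) in the expert group, with `delta_r` calibrated via
#' [calibrate_delta_r()].
#'
#' @inheritParams calibrate_delta_r
#' @param base Baseline correlation matrix (for the per-edge base r).
#' @return Tibble with columns `seed_a`, `seed_b`, `group`, `delta_r`.
#' @export
planted_pattern_experts <- function(base = default_base_correlation(),
                                    n_volumes = 90, band = NULL, tr_s = 2) {
  tibble::tibble(
    seed_a = c("R_IPS", "L44"),
    seed_b = c("R_CAUD", "R44"),
    group = "expert",
    delta_r = c(
      calibrate_delta_r(base["R_IPS", "R_CAUD"], 1.00, n_volumes, band, tr_s),
      calibrate_delta_r(base["L44", "R44"], -1.08, n_volumes, band, tr_s))
  )
}

#' Planted behavior--connectivity coupling
#'
#' Default coupling: within the expert group, the consensual creativity
#' rating is negatively coupled (target Spearman rho = -0.62) to the left
#' area 44 -- left temporal pole edge.
#'
#' @return Tibble with columns `seed_a`, `seed_b`, `score`, `group_scope`,
#'   `target_rho`.
#' @export
planted_behavior_couplings <- function() {
  tibble::tibble(seed_a = "L44", seed_b = "L_TP", score = "cr",
                 group_scope = "expert", target_rho = -0.62)
}

default_score_distributions <- function() {
  tibble::tribble(
    ~group,      ~score,           ~mean, ~sd,
    "expert",    "vci",            116.5,  9.9,
    "nonexpert", "vci",            107.1,  8.8,
    "expert",    "cr",               6.6,  1.3,
    "nonexpert", "cr",               5.2,  1.4,
    "expert",    "semester",         7.1,  3.9,
    "nonexpert", "semester",         0.0,  0.0,
    "expert",    "years_writing",   11.7,  4.8,
    "nonexpert", "years_writing",    3.1,  5.2,
    "expert",    "hours_per_week",  21.0, 10.2,
    "nonexpert", "hours_per_week",   0.5,  0.8
  )
}

default_confound_params <- function() {
  list(
    trans_step_mm = 0.02,    # random-walk step SD, translations
    rot_step_rad = 2e-4,     # random-walk step SD, rotations
    tissue_freq_hz = c(0.005, 0.03),  # tissue-signal oscillation range
    tissue_noise = 0.3,      # white noise on tissue signals
    confound_loading = 0.25, # SD of per-seed loadings onto confounds
    drift_amp = 0.5          # linear drift amplitude over a run
  )
}

#' Configure the synthetic two-group cohort
#'
#' Defaults reproduce the emulated study's design: 20 experts vs 23
#' non-experts, 10 seeds, TR = 2 s, two runs with five 10-volume inter-block
#' rests plus 5 end-of-run volumes (90 retained volumes per subject), the
#' expert connectivity pattern of [planted_pattern_experts()], and the
#' behavioral score distributions observed in the study.
#'
#' @param n_expert,n_nonexpert Group sizes (defaults 20 and 23).
#' @param seed_names Seed labels; their order fixes edge enumeration.
#' @param layout An [acquisition_layout()] (default [default_layout()]).
#' @param rest_cfg A [rest_selection_config()].
#' @param base_correlation Baseline correlation matrix
#'   (default [default_base_correlation()]).
#' @param planted_effects `NULL`, or a tibble with columns `seed_a`,
#'   `seed_b`, `group`, `delta_r` of group-specific correlation offsets.
#'   The default plants the expert pattern calibrated to the mode's
#'   analysis scale: in full mode the 0.01-0.08 Hz band-pass reduces the
#'   effective number of independent volumes, so the calibrated `delta_r`
#'   is larger (see [calibrate_delta_r()]).
#' @param behavior_couplings `NULL`, or a tibble with columns `seed_a`,
#'   `seed_b`, `score`, `group_scope`, `target_rho`.
#' @param score_distributions Per-group mean/SD tibble for the behavioral
#'   quantities (`vci`, `cr`, `semester`, `years_writing`, `hours_per_week`).
#' @param confound_params Amplitudes of the simulated confounds (full mode).
#' @param voxels_per_seed 1 for ROI mode; >= 2 expands each seed into a
#'   rank-1 voxel bundle plus voxel noise.
#' @param mode `"full"` simulates complete raw runs with confounds;
#'   `"rest_only"` draws the retained rest volumes directly (no confounds,
#'   no filtering), for fast replicate studies.
#' @param rng_seed Integer seed; fixes the cohort byte-for-byte.
#' @return An object of class `rfc_sim_config`.
#' @export
simulation_config <- function(n_expert = 20, n_nonexpert = 23,
                              seed_names = seed_set()$name,
                              layout = default_layout(),
                              rest_cfg = rest_selection_config(),
                              base_correlation = default_base_correlation(seed_names),
                              planted_effects = planted_pattern_experts(
                                base_correlation,
                                band = if (mode == "full") c(0.01, 0.08)),
                              behavior_couplings = planted_behavior_couplings(),
                              score_distributions = default_score_distributions(),
                              confound_params = default_confound_params(),
                              voxels_per_seed = 1,
                              mode = c("full", "rest_only"),
                              rng_seed = 1L) {
  mode <- match.arg(mode)
  n_expert <- check_count(n_expert, "n_expert", lower = 2L)
  n_nonexpert <- check_count(n_nonexpert, "n_nonexpert", lower = 2L)
  voxels_per_seed <- check_count(voxels_per_seed, "voxels_per_seed", lower = 1L)
  check_count(rng_seed, "rng_seed")
  check_matrix(base_correlation, "base_correlation")
  k <- length(seed_names)
  if (!all(dim(base_correlation) == k)) {
    stop_restfc("`base_correlation` must be seeds x seeds.")
  }
  if (max(abs(base_correlation - t(base_correlation))) > 1e-10 ||
      max(abs(diag(base_correlation) - 1)) > 1e-10) {
    stop_restfc("`base_correlation` must be symmetric with unit diagonal.")
  }
  if (is.null(dimnames(base_correlation))) {
    dimnames(base_correlation) <- list(seed_names, seed_names)
  }
  if (!is.null(planted_effects) && nrow(planted_effects)) {
    stopifnot(all(c("seed_a", "seed_b", "group", "delta_r") %in% names(planted_effects)))
    if (any(abs(planted_effects$delta_r) >= 1)) {
      stop_restfc("`delta_r` must satisfy |delta_r| < 1.")
    }
  }
  if (!is.null(behavior_couplings) && nrow(behavior_couplings)) {
    stopifnot(all(c("seed_a", "seed_b", "score", "group_scope", "target_rho")
                  %in% names(behavior_couplings)))
    if (any(abs(behavior_couplings$target_rho) >= 1)) {
      stop_restfc("`target_rho` must lie in (-1, 1).")
    }
    key <- paste(behavior_couplings$score, behavior_couplings$group_scope)
    if (anyDuplicated(key)) {
      stop_restfc("Inconsistent couplings: one score/group has two targets.")
    }
  }
  structure(
    list(n_expert = n_expert, n_nonexpert = n_nonexpert,
         seed_names = seed_names, layout = layout, rest_cfg = rest_cfg,
         base_correlation = base_correlation,
         planted_effects = planted_effects,
         behavior_couplings = behavior_couplings,
         score_distributions = score_distributions,
         confound_params = confound_params,
         voxels_per_seed = voxels_per_seed,
         mode = mode, rng_seed = as.integer(rng_seed)),
    class = "rfc_sim_config"
  )
}

#' Group covariance with planted edge effects
#'
#' Adds each planted `delta_r` for `group` to the corresponding off-diagonal
#' pair of the baseline correlation matrix. If the perturbed matrix loses
#' positive definiteness it is repaired by clipping eigenvalues at a small
#' floor and renormalizing the diagonal to 1 (reported via a message).
#'
#' @param base Symmetric unit-diagonal correlation matrix with dimnames.
#' @param effects `NULL` or tibble with `seed_a`, `seed_b`, `group`,
#'   `delta_r`.
#' @param group Group label whose effects apply.
#' @param eig_floor Eigenvalue floor for the repair (default 1e-4).
#' @return Symmetric positive-definite correlation matrix.
#' @export
build_group_covariance <- function(base, effects = NULL, group = "expert",
                                   eig_floor = 1e-4) {
  check_matrix(base, "base")
  if (max(abs(base - t(base))) > 1e-10 || max(abs(diag(base) - 1)) > 1e-10) {
    stop_restfc("`base` must be symmetric with unit diagonal.")
  }
  off <- base[upper.tri(base)]
  if (any(abs(off) >= 1)) stop_restfc("Off-diagonal entries must satisfy |r| < 1.")
  sigma <- base
  if (!is.null(effects) && nrow(effects)) {
    eff <- effects[effects$group == group, , drop = FALSE]
    for (e in seq_len(nrow(eff))) {
      a <- eff$seed_a[e]; b <- eff$seed_b[e]
      if (is.na(match(a, rownames(sigma))) || is.na(match(b, rownames(sigma)))) {
        stop_restfc(sprintf("Planted effect names unknown seed(s): %s, %s", a, b))
      }
      new_r <- sigma[a, b] + eff$delta_r[e]
      if (abs(new_r) >= 1) {
        stop_restfc(sprintf(
          "Perturbed correlation at (%s, %s) is %.3f, outside (-1, 1).", a, b, new_r))
      }
      sigma[a, b] <- sigma[b, a] <- new_r
    }
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < eig_floor) {
    rlang::inform(sprintf(
      "Repairing non-positive-definite group covariance (min eigenvalue %.2e); clipping at %.1e.",
      min(ev$values), eig_floor))
    vals <- pmax(ev$values, eig_floor)
    sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    sigma <- stats::cov2cor(sigma)
    sigma <- (sigma + t(sigma)) / 2
    dimnames(sigma) <- dimnames(base)
  }
  sigma
}

# confound signals for one raw run (n volumes): motion random walks,
# tissue oscillations; returned as a volumes x 9 matrix (canonical order)
simulate_confounds <- function(n, params) {
  motion <- vapply(seq_len(6L), function(j) {
    step <- if (j <= 3L) params$trans_step_mm else params$rot_step_rad
    cumsum(stats::rnorm(n, 0, step))
  }, numeric(n))
  tissue <- vapply(seq_len(3L), function(j) {
    f <- stats::runif(1, params$tissue_freq_hz[1], params$tissue_freq_hz[2])
    phase <- stats::runif(1, 0, 2 * pi)
    sin(2 * pi * f * 2 * seq_len(n) + phase) +
      stats::rnorm(n, 0, params$tissue_noise)
  }, numeric(n))
  conf <- cbind(motion, tissue)
  colnames(conf) <- canonical_confound_cols
  conf
}

#' Simulate one subject's raw data
#'
#' Draws the subject's ROI time series as correlated Gaussian noise under
#' the group covariance, plus (in full mode) linear combinations of
#' simulated confound signals (motion random walks, slow tissue
#' oscillations) and a slow drift. Output is bit-reproducible for a fixed
#' `rng_seed`.
#'
#' @param config An [simulation_config()].
#' @param group `"expert"` or `"nonexpert"`.
#' @param rng_seed Integer substream seed for this subject.
#' @return A list: in full mode `runs` (list of raw volumes x seeds
#'   matrices, including initial equilibration volumes), `confounds` (list
#'   of matching volumes x 9 confound matrices) and `latent_rest` (the
#'   confound-free retained rest series, volumes x seeds); in rest-only mode
#'   `rest_series` (= `latent_rest`). In voxel mode each run/rest matrix is
#'   expanded to volumes x (seeds * voxels_per_seed), each seed's voxels
#'   sharing its latent course plus voxel noise, with column names
#'   `<seed>.v<voxel>`.
#' @export
simulate_subject <- function(config, group, rng_seed) {
  stopifnot(inherits(config, "rfc_sim_config"))
  sigma <- build_group_covariance(config$base_correlation,
                                  config$planted_effects, group)
  R <- chol(sigma)
  k <- length(config$seed_names)
  sel <- select_rest_volumes(config$layout, config$rest_cfg)
  with_rng_seed(rng_seed, {
    if (config$mode == "rest_only") {
      n <- sel$n_total
      latent <- matrix(stats::rnorm(n * k), n, k) %*% R
      colnames(latent) <- config$seed_names
      out <- list(rest_series = expand_voxels(latent, config),
                  latent_rest = latent)
      return(out)
    }
    p <- config$confound_params
    discard <- config$rest_cfg$discard_run_initial_volumes
    n_run <- run_length(config$layout)
    runs <- vector("list", config$layout$runs)
    confs <- vector("list", config$layout$runs)
    latent_rest <- vector("list", config$layout$runs)
    for (r in seq_len(config$layout$runs)) {
      n <- discard + n_run
      latent <- matrix(stats::rnorm(n * k), n, k) %*% R
      conf <- simulate_confounds(n, p)
      conf_std <- scale(conf)
      loadings <- matrix(stats::rnorm(9L * k, 0, p$confound_loading), 9L, k)
      drift <- p$drift_amp * seq(-1, 1, length.out = n)
      series <- latent + conf_std %*% loadings + drift
      colnames(series) <- config$seed_names
      runs[[r]] <- expand_voxels(series, config)
      confs[[r]] <- conf
      latent_rest[[r]] <- latent[discard + sel$per_run[[r]] + 1L, , drop = FALSE]
    }
    latent_rest <- do.call(rbind, latent_rest)
    colnames(latent_rest) <- config$seed_names
    list(runs = runs, confounds = confs, latent_rest = latent_rest)
  })
}

# rank-1 voxel bundle per seed: voxel = weight * seed course + noise
expand_voxels <- function(series, config) {
  v <- config$voxels_per_seed
  if (v == 1L) return(series)
  k <- ncol(series); n <- nrow(series)
  cols <- vector("list", k)
  for (s in seq_len(k)) {
    w <- stats::runif(v, 0.8, 1.2)
    vox <- series[, s] %o% w + matrix(stats::rnorm(n * v, 0, 0.5), n, v)
    colnames(vox) <- paste0(colnames(series)[s], ".v", seq_len(v))
    cols[[s]] <- vox
  }
  do.call(cbind, cols)
}

#' Simulate behavioral scores coupled to connectivity
#'
#' Draws per-subject behavioral quantities from the configured per-group
#' distributions. A coupled score is a linear mix of the subject's
#' standardized edge Fisher-Z value and independent noise; the mixing weight
#' is `2 * sin(pi * target_rho / 6)` (the Pearson correlation that yields
#' the target Spearman correlation under bivariate normality). The practice
#' index is computed from simulated `semester`, `years_writing` and
#' `hours_per_week` via [practice_index()]; couplings may target `vci` or
#' `cr` only.
#'
#' @param cohort Tibble with columns `subject` and `group`.
#' @param edge_values Tibble with column `subject` plus one column per edge
#'   (Fisher-Z), covering every coupled edge.
#' @param couplings `NULL` or a coupling tibble
#'   (see [simulation_config()]).
#' @param score_distributions Per-group mean/SD tibble.
#' @param rng_seed Integer seed.
#' @return Tibble: `subject`, `semester`, `years_writing`, `hours_per_week`,
#'   `vci`, `cr`, `pi_score`.
#' @export
simulate_behavior <- function(cohort, edge_values = NULL, couplings = NULL,
                              score_distributions = default_score_distributions(),
                              rng_seed = 1L) {
  n <- nrow(cohort)
  if (!is.null(couplings) && nrow(couplings)) {
    key <- paste(couplings$score, couplings$group_scope)
    if (anyDuplicated(key)) {
      stop_restfc("Inconsistent couplings: one score/group has two targets.")
    }
    if (any(!couplings$score %in% c("vci", "cr"))) {
      stop_restfc("Couplings may target `vci` or `cr` only.")
    }
    if (is.null(edge_values)) {
      stop_restfc("`edge_values` required when couplings are present.")
    }
  }
  draw <- function(score, group_vec) {
    out <- numeric(n)
    for (g in unique(group_vec)) {
      row <- score_distributions[score_distributions$group == g &
                                 score_distributions$score == score, ]
      if (nrow(row) != 1L) {
        stop_restfc(sprintf("No score distribution for %s/%s.", g, score))
      }
      idx <- which(group_vec == g)
      out[idx] <- stats::rnorm(length(idx), row$mean, row$sd)
    }
    out
  }
  with_rng_seed(rng_seed, {
    g <- cohort$group
    semester <- pmax(0, draw("semester", g))
    years_writing <- pmax(0, draw("years_writing", g))
    hours_per_week <- pmax(0, draw("hours_per_week", g))
    vci <- draw("vci", g)
    cr <- pmin(10, pmax(0, draw("cr", g)))
    scores <- list(vci = vci, cr = cr)
    if (!is.null(couplings) && nrow(couplings)) {
      for (ci in seq_len(nrow(couplings))) {
        cc <- couplings[ci, ]
        edge <- paste0(cc$seed_a, "--", cc$seed_b)
        if (!edge %in% names(edge_values)) {
          stop_restfc(sprintf("Edge values missing coupled edge %s.", edge))
        }
        scope <- if (cc$group_scope == "all") rep(TRUE, n) else g == cc$group_scope
        if (!any(scope)) next
        m <- match(cohort$subject, edge_values$subject)
        x <- edge_values[[edge]][m][scope]
        if (anyNA(x)) stop_restfc("Edge values missing for coupled subjects.")
        x <- as.numeric(scale(x))
        rho_p <- 2 * sin(pi * cc$target_rho / 6)
        mixed <- rho_p * x + sqrt(1 - rho_p^2) * stats::rnorm(sum(scope))
        # rescale to the configured group mean/SD within the scope
        sc <- scores[[cc$score]]
        for (gg in unique(g[scope])) {
          row <- score_distributions[score_distributions$group == gg &
                                     score_distributions$score == cc$score, ]
          idx <- which(scope & g == gg)
          sc[idx] <- row$mean + row$sd * mixed[match(idx, which(scope))]
        }
        if (cc$score == "cr") sc <- pmin(10, pmax(0, sc))
        scores[[cc$score]] <- sc
      }
    }
    tibble::tibble(
      subject = cohort$subject,
      semester = semester, years_writing = years_writing,
      hours_per_week = hours_per_week,
      vci = scores$vci, cr = scores$cr,
      pi_score = practice_index(semester, years_writing, hours_per_week))
  })
}

#' Simulate a full two-group cohort
#'
#' Generates demographics (ages and sex composition matching the emulated
#' study), per-subject BOLD ROI series under the group covariances (with
#' confounds and block layout in full mode), and behavioral scores coupled
#' to the realized connectivity. Subjects use counter-based RNG substreams
#' of `config$rng_seed`, so cohorts are reproducible byte-for-byte and
#' subjects are independent.
#'
#' @param config An [simulation_config()].
#' @return An object of class `rfc_cohort`: a list with `cohort` (per-
#'   subject tibble: subject, group, age, sex, behavioral scores), `series`
#'   (per-subject simulation output of [simulate_subject()]), `latent_edges`
#'   (tibble of confound-free edge Fisher-Z values used for behavior
#'   coupling), `mode`, `layout`, and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "rfc_sim_config"))
  n <- config$n_expert + config$n_nonexpert
  groups <- c(rep("expert", config$n_expert), rep("nonexpert", config$n_nonexpert))
  subjects <- sprintf("sub-%03d", seq_len(n))

  demo <- with_rng_seed(substream_seed(config$rng_seed, 0), {
    age <- numeric(n)
    age[groups == "expert"] <- stats::rnorm(config$n_expert, 25.2, 2.7)
    age[groups == "nonexpert"] <- stats::rnorm(config$n_nonexpert, 24.0, 1.9)
    age <- pmax(18, age)
    # sex composition of the emulated study: 8 F / 12 M experts, 11 F / 12 M
    # non-experts (female = 0, male = 1), scaled to the configured sizes
    sex <- numeric(n)
    n_f_exp <- round(config$n_expert * 8 / 20)
    n_f_non <- round(config$n_nonexpert * 11 / 23)
    sex[groups == "expert"] <- sample(c(rep(0, n_f_exp),
                                        rep(1, config$n_expert - n_f_exp)))
    sex[groups == "nonexpert"] <- sample(c(rep(0, n_f_non),
                                           rep(1, config$n_nonexpert - n_f_non)))
    tibble::tibble(subject = subjects, group = groups, age = age, sex = sex)
  })

  series <- purrr::map(seq_len(n), function(i) {
    simulate_subject(config, groups[i], substream_seed(config$rng_seed, i))
  })
  names(series) <- subjects

  latent <- purrr::map(series, "latent_rest")
  latent_edges <- cohort_edge_table(latent, config$seed_names)

  behavior <- simulate_behavior(
    demo, latent_edges, config$behavior_couplings,
    config$score_distributions,
    rng_seed = substream_seed(config$rng_seed, n + 1L))

  structure(
    list(cohort = dplyr::left_join(demo, behavior, by = "subject"),
         series = series, latent_edges = latent_edges,
         mode = config$mode, layout = config$layout, config = config),
    class = "rfc_cohort"
  )
}

#' @export
print.rfc_cohort <- function(x, ...) {
  cat(sprintf("<rfc_cohort> %d subjects (%d expert / %d nonexpert), %d seeds, mode '%s'\n",
              nrow(x$cohort), sum(x$cohort$group == "expert"),
              sum(x$cohort$group == "nonexpert"),
              length(x$config$seed_names), x$mode))
  invisible(x)
}

#' Retained rest-volume ROI series of a simulated cohort
#'
#' For a rest-only cohort this is the simulated series itself; for a full
#' cohort the raw runs must first be preprocessed with
#' [preprocess_cohort()].
#'
#' @param cohort An `rfc_cohort`.
#' @return Named list of volumes x seeds matrices.
#' @export
rest_series <- function(cohort) {
  stopifnot(inherits(cohort, "rfc_cohort"))
  if (cohort$mode != "rest_only") {
    stop_restfc("Full-mode cohorts must be preprocessed; see preprocess_cohort().")
  }
  purrr::map(cohort$series, "rest_series")
}
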
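#' Configure edge-level group inference
#'
#' Thresholds follow the emulated study: 10,000 label permutations, a
#' posterior-probability threshold of 0.95 (uncorrected), an effect-size
#' gate requiring at least a small within-group connectivity effect
#' (r >= 0.10) and a large between-group difference (Cohen's d >= 0.80),
#' FDR alpha 0.05 for one-sample main effects, and for behavior
#' correlations p < 0.05 (uncorrected) with at least a medium effect
#' (|rho| >= 0.24).
#'
#' @param n_permutations Monte-Carlo label permutations (default 10000).
#' @param posterior_threshold Posterior-probability threshold (default 0.95).
#' @param r_small_effect Small-effect gate on group connectivity (default 0.10).
#' @param d_large_effect Large-effect gate on the group difference (default 0.80).
#' @param fdr_alpha Benjamini-Hochberg level for main effects (default 0.05).
#' @param rho_medium_effect Medium-effect gate on behavior correlations
#'   (default 0.24).
#' @param p_uncorrected Uncorrected p threshold for behavior correlations
#'   (default 0.05).
#' @param rng_seed Seed for the permutation generator.
#' @return An object of class `rfc_inference_config`.
#' @export
inference_config <- function(n_permutations = 10000,
                             posterior_threshold = 0.95,
                             r_small_effect = 0.10,
                             d_large_effect = 0.80,
                             fdr_alpha = 0.05,
                             rho_medium_effect = 0.24,
                             p_uncorrected = 0.05,
                             rng_seed = 1L) {
  structure(
    list(
      n_permutations = check_count(n_permutations, "n_permutations", lower = 1L),
      posterior_threshold = check_number(posterior_threshold, "posterior_threshold", 0, 1),
      r_small_effect = check_number(r_small_effect, "r_small_effect", 0, 1),
      d_large_effect = check_number(d_large_effect, "d_large_effect", 0),
      fdr_alpha = check_number(fdr_alpha, "fdr_alpha", 0, 1),
      rho_medium_effect = check_number(rho_medium_effect, "rho_medium_effect", 0, 1),
      p_uncorrected = check_number(p_uncorrected, "p_uncorrected", 0, 1),
      rng_seed = check_count(rng_seed, "rng_seed")
    ),
    class = "rfc_inference_config"
  )
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`, where the pooled SD weights group
#' variances by `n - 1`.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return Signed effect size.
#' @examples
#' cohens_d(c(1, 2, 3), c(0, 1, 2))  # 1
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_restfc("Both groups need >= 2 values.")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 < .Machine$double.eps) stop_restfc("Pooled SD is zero; d undefined.")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' One-sample main effects across edges with FDR
#'
#' Tests each edge's adjusted Fisher-Z values against 0 with a one-sample
#' t-test and flags edges surviving Benjamini-Hochberg FDR across edges.
#'
#' @param z Numeric subjects x edges matrix (or data frame of edge columns).
#' @param fdr_alpha FDR level (default 0.05).
#' @return Tibble: `edge`, `mean_z`, `t`, `p`, `p_fdr`, `fdr_main_effect`.
#'   Zero-variance edges get `NA` statistics (with a warning) and are never
#'   flagged.
#' @export
edge_main_effects <- function(z, fdr_alpha = 0.05) {
  z <- as.matrix(z)
  check_matrix(z, "z")
  n <- nrow(z)
  if (n < 3L) stop_restfc("Need at least 3 subjects.")
  edges <- colnames(z) %||% paste0("edge", seq_len(ncol(z)))
  mu <- unname(colMeans(z))
  s <- unname(apply(z, 2L, stats::sd))
  degenerate <- s < .Machine$double.eps
  if (any(degenerate)) {
    rlang::warn(sprintf("%d zero-variance edge(s) excluded from main-effect tests.",
                        sum(degenerate)))
  }
  tstat <- ifelse(degenerate & mu == 0, 0,
                  ifelse(degenerate, NA_real_, mu / (s / sqrt(n))))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p_fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  tibble::tibble(
    edge = edges, mean_z = mu, t = tstat, p = p, p_fdr = p_fdr,
    fdr_main_effect = !is.na(p_fdr) & p_fdr < fdr_alpha & s > .Machine$double.eps)
}

# median of each column of a k x P matrix (single vectorized sort)
col_medians <- function(m) {
  k <- nrow(m)
  o <- order(rep.int(seq_len(ncol(m)), rep.int(k, ncol(m))), m)
  s <- matrix(m[o], nrow = k)
  if (k %% 2L) s[(k + 1L) %/% 2L, ] else (s[k %/% 2L, ] + s[k %/% 2L + 1L, ]) / 2
}

# one shared permutation set (columns = permuted subject orderings)
permutation_set <- function(n_subjects, n_perm, rng_seed) {
  with_rng_seed(rng_seed, {
    matrix(vapply(seq_len(n_perm), function(b) sample.int(n_subjects),
                  integer(n_subjects)), n_subjects, n_perm)
  })
}

# core engine: observed median differences and one-sided posterior
# probabilities for all edges, reusing one permutation set across edges
perm_median_posteriors <- function(z_matrix, is_expert, perms) {
  n <- nrow(z_matrix)
  n1 <- sum(is_expert)
  ord <- c(which(is_expert), which(!is_expert))
  z_matrix <- z_matrix[ord, , drop = FALSE]
  n_perm <- ncol(perms)
  observed <- numeric(ncol(z_matrix))
  posterior <- numeric(ncol(z_matrix))
  for (e in seq_len(ncol(z_matrix))) {
    zc <- z_matrix[, e]
    obs <- stats::median(zc[seq_len(n1)]) - stats::median(zc[-seq_len(n1)])
    if (stats::sd(zc) < .Machine$double.eps) {
      rlang::warn("Degenerate edge: all values identical; posterior set to 0.5.")
      observed[e] <- obs; posterior[e] <- 0.5
      next
    }
    zp <- matrix(zc[perms], n, n_perm)
    null <- col_medians(zp[seq_len(n1), , drop = FALSE]) -
      col_medians(zp[(n1 + 1L):n, , drop = FALSE])
    observed[e] <- obs
    posterior[e] <- (1 + sum(null < obs)) / (1 + n_perm)
  }
  list(observed = observed, posterior = posterior,
       posterior_dir = pmax(posterior, 1 - posterior))
}

#' Monte-Carlo median permutation test for one edge
#'
#' Compares group medians via group-label exchangeability: the observed
#' statistic is `median(expert) - median(nonexpert)`; the null distribution
#' is built from `n_permutations` random label reassignments preserving
#' group sizes. The posterior probability is the add-one-smoothed position
#' of the observed statistic in the null distribution,
#' `(1 + #\{null < observed\}) / (1 + B)`: it is calibrated at 0.5 under
#' exchangeability, maps to `1 - p` when group labels are swapped, and is
#' never exactly 0 or 1. Its directional fold `max(p, 1 - p)` —
#' `posterior_dir` — is the probability that a null realization is less
#' extreme than the observed difference in the observed direction, the
#' quantity thresholded by the effect gate.
#'
#' @param expert_z,nonexpert_z Numeric vectors (length >= 2 each).
#' @param cfg An [inference_config()] (permutation count and seed).
#' @return List with `observed` (median difference), `posterior` and its
#'   directional fold `posterior_dir`.
#' @export
median_diff_perm_test <- function(expert_z, nonexpert_z,
                                  cfg = inference_config()) {
  if (length(expert_z) < 2L || length(nonexpert_z) < 2L) {
    stop_restfc("Both groups need >= 2 subjects.")
  }
  z <- matrix(c(expert_z, nonexpert_z), ncol = 1L)
  is_expert <- c(rep(TRUE, length(expert_z)), rep(FALSE, length(nonexpert_z)))
  perms <- permutation_set(length(is_expert), cfg$n_permutations, cfg$rng_seed)
  res <- perm_median_posteriors(z, is_expert, perms)
  list(observed = res$observed[1], posterior = res$posterior[1],
       posterior_dir = res$posterior_dir[1])
}

#' Apply the effect-size gates to an edge statistics table
#'
#' An edge is `flagged` iff its directional posterior probability
#' (`max(posterior, 1 - posterior)`, the probability that a null
#' realization is less extreme than the observed difference in the
#' observed direction) exceeds `posterior_threshold` AND either group's
#' connectivity corresponds to at least a small effect (|r| of the
#' back-transformed group median Fisher-Z >= `r_small_effect`) AND the
#' group difference is large (|d| >= `d_large_effect`).
#'
#' @param stats Tibble with columns `posterior`, `r_expert`, `r_nonexpert`,
#'   `d`.
#' @param cfg An [inference_config()].
#' @return `stats` with logical columns `posterior_pass`, `r_gate_pass`,
#'   `d_gate_pass`, `flagged` added/replaced.
#' @export
gate_edges <- function(stats, cfg = inference_config()) {
  needed <- c("posterior", "r_expert", "r_nonexpert", "d")
  if (!all(needed %in% names(stats))) {
    stop_restfc(paste0("`stats` needs columns: ", paste(needed, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(stats),
    posterior_pass = pmax(.data$posterior, 1 - .data$posterior) > cfg$posterior_threshold,
    r_gate_pass = pmax(abs(.data$r_expert), abs(.data$r_nonexpert)) >= cfg$r_small_effect,
    d_gate_pass = abs(.data$d) >= cfg$d_large_effect,
    flagged = .data$posterior_pass & .data$r_gate_pass & .data$d_gate_pass)
}

#' Expert vs non-expert edge test with effect-size gating
#'
#' Runs the full group-difference procedure on an (age/sex-adjusted)
#' subjects x edges table: group medians and their difference, the
#' Monte-Carlo median permutation posterior (one shared permutation set
#' across edges, preserving the cross-edge dependence of the null), Cohen's
#' d, per-group effect size r (back-transform of the group median Fisher-Z),
#' the effect-size gates, and one-sample main effects with FDR.
#'
#' @param edge_tbl Tibble from [cohort_edge_table()] (adjusted via
#'   [adjust_edge_table()]), column `subject` plus edge columns.
#' @param cohort Tibble with columns `subject` and `group`
#'   (`"expert"`/`"nonexpert"`).
#' @param cfg An [inference_config()].
#' @return An object of class `rfc_edge_test`; see [tidy.rfc_edge_test()].
#' @export
rfc_group_test <- function(edge_tbl, cohort, cfg = inference_config()) {
  if (!"subject" %in% names(edge_tbl)) stop_restfc("`edge_tbl` needs a `subject` column.")
  m <- match(edge_tbl$subject, cohort$subject)
  if (anyNA(m)) stop_restfc("Subjects in `edge_tbl` missing from `cohort`.")
  group <- cohort$group[m]
  if (!all(group %in% c("expert", "nonexpert"))) {
    stop_restfc("`group` must be 'expert' or 'nonexpert'.")
  }
  z <- as.matrix(edge_tbl[, setdiff(names(edge_tbl), "subject")])
  is_expert <- group == "expert"
  if (sum(is_expert) < 2L || sum(!is_expert) < 2L) {
    stop_restfc("Both groups need >= 2 subjects.")
  }
  perms <- permutation_set(nrow(z), cfg$n_permutations, cfg$rng_seed)
  perm <- perm_median_posteriors(z, is_expert, perms)
  med_e <- unname(apply(z[is_expert, , drop = FALSE], 2L, stats::median))
  med_n <- unname(apply(z[!is_expert, , drop = FALSE], 2L, stats::median))
  d <- vapply(seq_len(ncol(z)),
              function(e) cohens_d(z[is_expert, e], z[!is_expert, e]),
              numeric(1))
  stats_tbl <- tibble::tibble(
    edge = colnames(z),
    median_expert = med_e,
    median_nonexpert = med_n,
    median_diff = perm$observed,
    posterior = perm$posterior,
    posterior_dir = perm$posterior_dir,
    r_expert = inverse_fisher_z(med_e),
    r_nonexpert = inverse_fisher_z(med_n),
    d = d)
  stats_tbl <- gate_edges(stats_tbl, cfg)
  main <- edge_main_effects(z, fdr_alpha = cfg$fdr_alpha)
  stats_tbl <- dplyr::left_join(stats_tbl, main, by = "edge")
  structure(
    list(edges = stats_tbl, config = cfg,
         n_expert = sum(is_expert), n_nonexpert = sum(!is_expert)),
    class = "rfc_edge_test"
  )
}

#' @export
print.rfc_edge_test <- function(x, ...) {
  cat(sprintf("<rfc_edge_test> %d edges, n = %d expert / %d nonexpert, %d permutation(s)\n",
              nrow(x$edges), x$n_expert, x$n_nonexpert, x$config$n_permutations))
  flagged <- x$edges$edge[x$edges$flagged]
  cat(sprintf("  flagged group differences: %s\n",
              if (length(flagged)) paste(flagged, collapse = ", ") else "none"))
  invisible(x)
}

#' Tidy an edge test into a per-edge tibble
#'
#' @param x An `rfc_edge_test`.
#' @param ... Unused.
#' @return The per-edge statistics tibble (medians, posterior, effect
#'   sizes, gate flags, main-effect t/p/FDR).
#' @method tidy rfc_edge_test
#' @export
tidy.rfc_edge_test <- function(x, ...) x$edges

#' One-row summary of an edge test
#'
#' @param x An `rfc_edge_test`.
#' @param ... Unused.
#' @return Tibble with group sizes, edge counts, permutations, and numbers
#'   of flagged edges.
#' @method glance rfc_edge_test
#' @export
glance.rfc_edge_test <- function(x, ...) {
  tibble::tibble(
    n_expert = x$n_expert, n_nonexpert = x$n_nonexpert,
    n_edges = nrow(x$edges),
    n_permutations = x$config$n_permutations,
    n_flagged = sum(x$edges$flagged),
    n_fdr_main = sum(x$edges$fdr_main_effect, na.rm = TRUE))
}

#' Plot edge-wise group differences
#'
#' Median Fisher-Z difference (expert - nonexpert) per edge, highlighting
#' edges passing the full gate.
#'
#' @param object An `rfc_edge_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rfc_edge_test
#' @export
autoplot.rfc_edge_test <- function(object, ...) {
  df <- object$edges
  df$edge <- stats::reorder(df$edge, df$median_diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_diff, y = .data$edge,
                                   colour = .data$flagged)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "median Fisher-Z difference (expert - nonexpert)",
                  y = NULL, colour = "flagged") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Spearman correlation of edges with a behavioral score
#'
#' Rank-correlates each edge's (adjusted) Fisher-Z values with an (adjusted)
#' behavioral score, using average ranks for ties and the t-approximation
#' for p-values. An edge-score pair is flagged when p is below the
#' uncorrected threshold and |rho| reaches at least a medium effect.
#'
#' @param edge_tbl Subjects x edges tibble (column `subject` + edge columns).
#' @param score Numeric per-subject score, aligned with `edge_tbl` rows.
#' @param cfg An [inference_config()].
#' @return Tibble: `edge`, `rho`, `p`, `flagged`.
#' @export
spearman_edge_behavior <- function(edge_tbl, score, cfg = inference_config()) {
  z <- as.matrix(edge_tbl[, setdiff(names(edge_tbl), "subject"), drop = FALSE])
  n <- nrow(z)
  if (n < 5L) stop_restfc("Need at least 5 subjects.")
  if (length(score) != n) stop_restfc("`score` must match the number of subjects.")
  if (stats::sd(score) < .Machine$double.eps) {
    stop_restfc("`score` is constant; Spearman correlation undefined.")
  }
  rs <- rank(score)
  rho <- unname(apply(z, 2L, function(col) stats::cor(rank(col), rs)))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  tibble::tibble(
    edge = colnames(z), rho = rho, p = p,
    flagged = p < cfg$p_uncorrected & abs(rho) >= cfg$rho_medium_effect)
}
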
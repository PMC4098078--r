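#' Pearson correlation matrix of seed time courses
#'
#' @param roi_series Numeric matrix, volumes x seeds (column names are seed
#'   labels).
#' @return Symmetric seeds x seeds Pearson correlation matrix with unit
#'   diagonal.
#' @export
pearson_matrix <- function(roi_series) {
  y <- as.matrix(roi_series)
  check_matrix(y, "roi_series")
  if (nrow(y) < 3L) stop_restfc("Need at least 3 volumes to correlate.")
  sds <- apply(y, 2L, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    bad <- colnames(y)[sds < .Machine$double.eps] %||% which(sds < .Machine$double.eps)
    stop_restfc(paste0("Zero-variance seed channel(s): ",
                       paste(bad, collapse = ", ")))
  }
  stats::cor(y)
}

#' Fisher's Z transform and its inverse
#'
#' `fisher_z()` maps a correlation r to z = atanh(r) = 0.5 * log((1+r)/(1-r));
#' `inverse_fisher_z()` maps back via tanh.
#'
#' @param r Correlation value(s), |r| < 1.
#' @param z Fisher-Z value(s).
#' @return Numeric vector/matrix of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop_restfc("Fisher's Z is undefined for |r| >= 1.")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Per-subject Fisher-Z connectivity matrix
#'
#' Correlates every pair of seed time courses on the retained rest volumes
#' and Fisher-Z transforms the result. The diagonal is set to `NA` (self-
#' connectivity is undefined).
#'
#' @inheritParams pearson_matrix
#' @return Seeds x seeds matrix of Fisher-Z scores, diagonal `NA`.
#' @export
connectivity_matrix <- function(roi_series) {
  r <- pearson_matrix(roi_series)
  diag(r) <- NA_real_
  z <- suppressWarnings(atanh(r))
  if (any(!is.finite(z[upper.tri(z)]))) {
    stop_restfc("Perfect correlation between distinct seeds; Fisher's Z diverges.")
  }
  z
}

#' Subjects x edges table of Fisher-Z values
#'
#' Flattens each subject's connectivity matrix into the canonical edge order
#' (upper triangle, row-major in seed order) and stacks subjects into a tidy
#' table, one row per subject, one column per edge.
#'
#' @param series_list Named list of per-subject ROI series matrices
#'   (volumes x seeds, identical column order).
#' @param seed_names Seed order defining edge enumeration; defaults to the
#'   column names of the first series.
#' @return A tibble with column `subject` followed by one numeric column per
#'   edge, labelled `"A--B"`.
#' @export
cohort_edge_table <- function(series_list, seed_names = NULL) {
  if (!length(series_list)) stop_restfc("`series_list` is empty.")
  if (is.null(names(series_list))) {
    names(series_list) <- sprintf("sub-%03d", seq_along(series_list))
  }
  seed_names <- seed_names %||% colnames(series_list[[1]])
  if (is.null(seed_names)) {
    seed_names <- paste0("seed", seq_len(ncol(series_list[[1]])))
  }
  edges <- edge_table(seed_names)
  vals <- vapply(series_list, function(mat) {
    z <- connectivity_matrix(mat)
    z[cbind(edges$i, edges$j)]
  }, numeric(nrow(edges)))
  out <- tibble::as_tibble(t(vals), .name_repair = "minimal")
  names(out) <- edges$edge
  dplyr::bind_cols(tibble::tibble(subject = names(series_list)), out)
}

#' Partial age and sex out of a variable
#'
#' Regresses per-subject values on age and sex (plus an intercept) and
#' returns the covariate-adjusted values: OLS residuals with the grand mean
#' retained, so that adjusted values remain on the original scale and carry
#' zero correlation with age and sex. The same operation is applied to
#' connectivity edge values and to behavioral scores before any group test
#' or correlation.
#'
#' @param values Numeric per-subject vector.
#' @param age Numeric per-subject ages (years).
#' @param sex Per-subject binary sex code (female = 0, male = 1).
#' @param keep_mean Retain the grand mean in the adjusted values (default
#'   `TRUE`); `FALSE` returns plain mean-zero residuals.
#' @return Numeric vector of adjusted values.
#' @export
adjust_covariates <- function(values, age, sex, keep_mean = TRUE) {
  n <- length(values)
  if (n < 4L || length(age) != n || length(sex) != n) {
    stop_restfc("`values`, `age` and `sex` must have equal length >= 4.")
  }
  if (!all(is.finite(values)) || !all(is.finite(age)) || !all(is.finite(sex))) {
    stop_restfc("Inputs must be finite.")
  }
  x <- cbind(intercept = 1, age = age, sex = as.numeric(sex))
  const <- apply(x[, -1L, drop = FALSE], 2L, function(col) stats::sd(col) < 1e-12)
  if (any(const)) {
    rlang::warn(paste0("Dropping constant covariate(s): ",
                       paste(names(const)[const], collapse = ", ")))
    x <- x[, c(TRUE, !const), drop = FALSE]
  }
  fit <- stats::lm.fit(x, values)
  res <- fit$residuals
  if (keep_mean) res <- res + mean(values)
  as.numeric(res)
}

#' Adjust every edge column of a subjects x edges table
#'
#' Applies [adjust_covariates()] to each edge column, taking `age` and `sex`
#' from a cohort table matched on `subject`.
#'
#' @param edge_tbl Tibble from [cohort_edge_table()].
#' @param cohort Tibble with columns `subject`, `age`, `sex`.
#' @inheritParams adjust_covariates
#' @return Tibble of the same shape as `edge_tbl` with adjusted values.
#' @export
adjust_edge_table <- function(edge_tbl, cohort, keep_mean = TRUE) {
  if (!"subject" %in% names(edge_tbl)) stop_restfc("`edge_tbl` needs a `subject` column.")
  m <- match(edge_tbl$subject, cohort$subject)
  if (anyNA(m)) stop_restfc("Some subjects in `edge_tbl` are missing from `cohort`.")
  age <- cohort$age[m]; sex <- cohort$sex[m]
  dplyr::mutate(edge_tbl, dplyr::across(
    -"subject", ~ adjust_covariates(.x, age, sex, keep_mean = keep_mean)))
}
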
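#' Backward-difference temporal derivative
#'
#' First derivative of a signal sampled at the volume rate, computed as the
#' backward difference with the first element set to 0.
#'
#' @param series Numeric vector (length >= 2).
#' @return Numeric vector of the same length.
#' @export
temporal_derivative <- function(series) {
  if (!is.numeric(series) || length(series) < 2L) {
    stop_restfc("`series` must be a numeric vector of length >= 2.")
  }
  c(0, diff(series))
}

canonical_confound_cols <- c("trans_x", "trans_y", "trans_z",
                             "rot_x", "rot_y", "rot_z",
                             "tissue_gm", "tissue_wm", "tissue_csf")

#' Build the 30-regressor nuisance design
#'
#' Columns, in order: the six rigid-body motion parameters; their backward-
#' difference temporal derivatives; the three tissue-class mean signals
#' (gray matter, white matter, CSF); and the elementwise squares of all 15
#' first-order regressors — 30 columns total. An intercept is added at
#' regression time and is not counted here.
#'
#' @param motion Numeric matrix or data frame, volumes x 6.
#' @param tissue Numeric matrix or data frame, volumes x 3.
#' @return A list of class `rfc_nuisance_design` with elements `matrix`
#'   (volumes x 30) and `column_names`.
#' @export
build_nuisance_matrix <- function(motion, tissue) {
  motion <- as.matrix(motion); tissue <- as.matrix(tissue)
  check_matrix(motion, "motion"); check_matrix(tissue, "tissue")
  if (ncol(motion) != 6L) stop_restfc("`motion` must have 6 columns.")
  if (ncol(tissue) != 3L) stop_restfc("`tissue` must have 3 columns.")
  if (nrow(motion) != nrow(tissue)) {
    stop_restfc("`motion` and `tissue` must cover the same volumes.")
  }
  deriv <- apply(motion, 2L, temporal_derivative)
  first_order <- cbind(motion, deriv, tissue)
  design <- cbind(first_order, first_order^2)
  motion_names <- canonical_confound_cols[1:6]
  tissue_names <- canonical_confound_cols[7:9]
  nm <- c(motion_names, paste0("d_", motion_names), tissue_names)
  colnames(design) <- c(nm, paste0(nm, "_sq"))
  structure(list(matrix = design, column_names = colnames(design)),
            class = "rfc_nuisance_design")
}

#' Remove nuisance variance by ordinary least squares
#'
#' Regresses each channel on the nuisance design (plus an intercept) and
#' returns the residuals. Rank deficiency is handled by the pivoted QR inside
#' `lm.fit`, with a warning.
#'
#' @param series_matrix Numeric matrix, volumes x channels.
#' @param design An `rfc_nuisance_design` from [build_nuisance_matrix()], or
#'   a plain numeric matrix of regressors.
#' @return Residual matrix, volumes x channels.
#' @export
residualize <- function(series_matrix, design) {
  y <- as.matrix(series_matrix)
  check_matrix(y, "series_matrix")
  x <- if (inherits(design, "rfc_nuisance_design")) design$matrix else as.matrix(design)
  check_matrix(x, "design")
  if (nrow(x) != nrow(y)) {
    stop_restfc("`series_matrix` and `design` must have the same number of volumes.")
  }
  x <- cbind(`(intercept)` = 1, x)
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    rlang::warn(sprintf(
      "Nuisance design is rank deficient (rank %d of %d columns); using pivoted least squares.",
      fit$rank, ncol(x)))
  }
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(y)
  res
}

#' Zero-phase band-pass filter for BOLD series
#'
#' Order-2 Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), preserving fluctuations between `low_hz` and
#' `high_hz` with zero phase shift. Applied per channel to full continuous
#' runs; rest volumes are extracted afterwards (a 16-s rest snippet cannot
#' express a 0.01 Hz cycle).
#'
#' @param series_matrix Numeric matrix (volumes x channels) or vector.
#' @param tr_s Repetition time in seconds.
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.01 and 0.08).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(series_matrix, tr_s, low_hz = 0.01, high_hz = 0.08) {
  vec_in <- is.null(dim(series_matrix))
  y <- as.matrix(series_matrix)
  check_matrix(y, "series_matrix")
  check_number(tr_s, "tr_s", lower = 1e-6)
  nyquist <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop_restfc(sprintf(
      "Band edges must satisfy 0 < low < high < Nyquist (%.4g Hz).", nyquist))
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  min_len <- 3L * (max(length(bf$a), length(bf$b)) - 1L) + 1L
  if (nrow(y) < max(min_len, 12L)) {
    stop_restfc(paste0(
      "Segment too short to band-pass filter (", nrow(y), " volumes). ",
      "Filter full continuous runs before extracting rest volumes."))
  }
  # demean (the passband excludes DC anyway) and attach an odd-reflection
  # extension at both ends so filtfilt's zero initial state does not leak
  # edge transients into the run
  out <- apply(y, 2L, function(ch) {
    n <- length(ch)
    ch <- ch - mean(ch)
    p <- min(n - 1L, 50L)
    ext <- c(2 * ch[1] - rev(ch[2:(p + 1)]), ch,
             2 * ch[n] - rev(ch[(n - p):(n - 1)]))
    signal::filtfilt(bf, ext)[(p + 1):(p + n)]
  })
  dimnames(out) <- dimnames(y)
  if (vec_in) drop(out) else out
}
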
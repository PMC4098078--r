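#' Extract seed eigenvariate time courses from a 4D NIfTI image
#'
#' For each seed, collects the voxels whose centers fall inside the sphere
#' ([sphere_voxels()]), optionally restricts them to gray matter via a
#' companion probability image (threshold 0.5), and reduces them to the
#' first eigenvariate.
#'
#' @param bold_path Path to a 4D NIfTI-1 BOLD image.
#' @param seeds Seed tibble ([seed_set()] format).
#' @param gm_mask_path Optional path to a 3D gray-matter probability image
#'   on the same grid.
#' @param gm_threshold Gray-matter probability cutoff (default 0.5).
#' @return Volumes x seeds matrix of eigenvariate time courses.
#' @export
extract_seed_series <- function(bold_path, seeds, gm_mask_path = NULL,
                                gm_threshold = 0.5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_restfc("Package 'RNifti' is required to read NIfTI images.")
  }
  img <- RNifti::readNifti(bold_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop_restfc("`bold_path` must be a 4D image.")
  affine <- structure(RNifti::xform(img), class = NULL)
  dims <- dim(arr)[1:3]
  gm <- NULL
  if (!is.null(gm_mask_path)) {
    gm_img <- as.array(RNifti::readNifti(gm_mask_path))
    if (!all(dim(gm_img)[1:3] == dims)) {
      stop_restfc("Gray-matter mask grid does not match the BOLD grid.")
    }
    gm <- gm_img >= gm_threshold
  }
  seeds <- validate_seed_set(seeds)
  n_vol <- dim(arr)[4]
  out <- matrix(NA_real_, n_vol, nrow(seeds),
                dimnames = list(NULL, seeds$name))
  flat <- matrix(arr, prod(dims), n_vol)
  for (s in seq_len(nrow(seeds))) {
    vox <- sphere_voxels(c(seeds$x_mm[s], seeds$y_mm[s], seeds$z_mm[s]),
                         seeds$radius_mm[s], affine, dims)
    lin <- vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1L
    mask <- if (is.null(gm)) NULL else gm[lin]
    out[, s] <- first_eigenvariate(t(flat[lin, , drop = FALSE]),
                                   mask = mask, seed_name = seeds$name[s])
  }
  out
}

#' Write a simulated voxel-mode subject as NIfTI
#'
#' Lays each seed's voxel bundle out as a compact synthetic 4D volume on a
#' 1.5-mm isotropic grid: the voxels of seed `s` fill a small neighborhood
#' around the seed center, so [extract_seed_series()] can recover the seed
#' time courses. Intended for round-trip testing of the NIfTI path, not as
#' an anatomically faithful phantom.
#'
#' @param series Volumes x (seeds * voxels) matrix with columns
#'   `<seed>.v<k>` (from [simulate_subject()] in voxel mode).
#' @param seeds Seed tibble; grid and affine are derived from its bounding
#'   box.
#' @param path Output `.nii` path.
#' @param voxel_mm Isotropic voxel size (default 1.5).
#' @return Invisibly, a list with `path`, `affine`, `dim`.
#' @export
write_voxel_nifti <- function(series, seeds, path, voxel_mm = 1.5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_restfc("Package 'RNifti' is required to write NIfTI images.")
  }
  seeds <- validate_seed_set(seeds)
  pad <- max(seeds$radius_mm) + 3 * voxel_mm
  origin <- c(min(seeds$x_mm), min(seeds$y_mm), min(seeds$z_mm)) - pad
  extent <- c(max(seeds$x_mm), max(seeds$y_mm), max(seeds$z_mm)) + pad - origin
  dims <- as.integer(ceiling(extent / voxel_mm)) + 1L
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- origin
  n_vol <- nrow(series)
  arr <- array(0, dim = c(dims, n_vol))
  flat <- matrix(arr, prod(dims), n_vol)
  for (s in seq_len(nrow(seeds))) {
    cols <- grep(paste0("^", seeds$name[s], "\\.v[0-9]+$"), colnames(series))
    if (!length(cols)) cols <- which(colnames(series) == seeds$name[s])
    if (!length(cols)) stop_restfc(sprintf("No columns for seed '%s'.", seeds$name[s]))
    vox <- sphere_voxels(c(seeds$x_mm[s], seeds$y_mm[s], seeds$z_mm[s]),
                         seeds$radius_mm[s], affine, dims)
    if (nrow(vox) < length(cols)) {
      stop_restfc("Sphere has fewer grid voxels than simulated voxel courses.")
    }
    lin <- vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1L
    # cycle the simulated voxel courses over the sphere's grid voxels
    assign_cols <- rep_len(cols, length(lin))
    flat[lin, ] <- t(series[, assign_cols, drop = FALSE])
  }
  arr <- array(flat, dim = c(dims, n_vol))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(list(path = path, affine = affine, dim = dims))
}
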
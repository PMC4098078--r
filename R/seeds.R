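#' Seed regions of the creative-writing resting-state network
#'
#' Returns the default seed set: ten 5-mm spheres centered on MNI-space
#' activation peaks previously associated with creative text generation
#' (bilateral posterior area 44, medial cingulate cortex, bilateral
#' intraparietal sulcus, left hippocampus, left temporal pole, left posterior
#' superior temporal sulcus, and bilateral caudate nucleus). Edge enumeration
#' throughout the package derives from the row order of this table (upper
#' triangle, row-major), giving 45 edges for 10 seeds.
#'
#' @param file Optional path to a seed TSV with columns `name`, `x_mm`,
#'   `y_mm`, `z_mm`, `radius_mm`. When `NULL` the packaged default set is
#'   returned.
#' @return A tibble with columns `name`, `x_mm`, `y_mm`, `z_mm`, `radius_mm`.
#' @examples
#' seed_set()
#' @export
seed_set <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "seeds_creative_writing.tsv",
                        package = "restfc", mustWork = TRUE)
  }
  seeds <- readr::read_tsv(file, show_col_types = FALSE,
                           col_types = readr::cols(
                             name = readr::col_character(),
                             .default = readr::col_double()
                           ))
  validate_seed_set(seeds)
}

validate_seed_set <- function(seeds) {
  required <- c("name", "x_mm", "y_mm", "z_mm", "radius_mm")
  missing <- setdiff(required, names(seeds))
  if (length(missing)) {
    stop_restfc(paste0("Seed table is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(seeds) < 2L) stop_restfc("A seed set needs at least 2 seeds.")
  if (anyDuplicated(seeds$name)) stop_restfc("Seed names must be unique.")
  if (any(seeds$radius_mm <= 0)) stop_restfc("Seed radii must be positive.")
  tibble::as_tibble(seeds[, required])
}

#' Enumerate seed pairs (edges) in canonical order
#'
#' Edges are the upper triangle of the seeds x seeds matrix in seed-set row
#' order, traversed row-major, labelled `"A--B"`.
#'
#' @param seed_names Character vector of seed names in canonical order.
#' @return A tibble with columns `edge`, `seed_a`, `seed_b`, `i`, `j`
#'   (1-based indices into `seed_names`, `i < j`).
#' @export
edge_table <- function(seed_names) {
  k <- length(seed_names)
  if (k < 2L) stop_restfc("Need at least 2 seeds to enumerate edges.")
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble::tibble(
    seed_a = seed_names[idx[, "row"]],
    seed_b = seed_names[idx[, "col"]],
    i = as.integer(idx[, "row"]),
    j = as.integer(idx[, "col"]),
    edge = paste0(seed_names[idx[, "row"]], "--", seed_names[idx[, "col"]])
  )[, c("edge", "seed_a", "seed_b", "i", "j")]
}

#' Voxels inside a spherical seed
#'
#' Selects all voxels of a grid whose centers lie within `radius_mm` of the
#' seed center, using the grid's affine to map 0-based voxel indices to
#' MNI millimetres.
#'
#' @param center_mm Numeric length-3, seed center in mm (MNI).
#' @param radius_mm Sphere radius in mm.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to mm.
#' @param dim Integer length-3 grid dimensions.
#' @return Integer matrix (voxels x 3) of 0-based voxel indices.
#' @export
sphere_voxels <- function(center_mm, radius_mm, affine, dim) {
  if (length(center_mm) != 3L) stop_restfc("`center_mm` must have length 3.")
  check_number(radius_mm, "radius_mm", lower = 1e-9)
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop_restfc("`affine` must be a 4x4 matrix.")
  }
  dim <- vapply(dim, function(d) check_count(d, "dim", lower = 1L), integer(1))

  inv <- solve(affine)
  vox_center <- (inv %*% c(center_mm, 1))[1:3]
  if (any(vox_center < -0.5) || any(vox_center > dim - 0.5)) {
    stop_restfc(sprintf(
      "Seed center (%s) mm maps outside the grid field of view.",
      paste(format(center_mm), collapse = ", ")))
  }

  # bounding box in voxel units, conservative for anisotropic grids
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  lo <- pmax(0L, floor(vox_center - radius_mm / spacing - 1))
  hi <- pmin(dim - 1L, ceiling(vox_center + radius_mm / spacing + 1))
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- t(affine %*% rbind(t(grid), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  keep <- grid[d2 <= radius_mm^2, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop_restfc("Sphere contains no voxel centers; radius too small for this grid.")
  }
  storage.mode(keep) <- "integer"
  dimnames(keep) <- list(NULL, c("i", "j", "k"))
  keep
}

#' First eigenvariate of a seed's voxel time courses
#'
#' Reduces a volumes x voxels matrix to the seed's summary time course: the
#' first left singular vector of the column-centered data, scaled to unit
#' variance, with sign fixed so that its correlation with the seed-mean time
#' course is non-negative.
#'
#' @param voxel_matrix Numeric matrix, volumes x voxels.
#' @param mask Optional logical per-voxel vector (e.g. gray-matter mask);
#'   voxels with `FALSE` are excluded.
#' @param seed_name Seed label used in error messages.
#' @return Numeric vector of length `nrow(voxel_matrix)`, zero mean, unit
#'   variance.
#' @export
first_eigenvariate <- function(voxel_matrix, mask = NULL, seed_name = "seed") {
  check_matrix(voxel_matrix, "voxel_matrix")
  if (nrow(voxel_matrix) < 2L) stop_restfc("Need at least 2 volumes.")
  if (!is.null(mask)) {
    if (length(mask) != ncol(voxel_matrix)) {
      stop_restfc("`mask` length must equal the number of voxels.")
    }
    voxel_matrix <- voxel_matrix[, as.logical(mask), drop = FALSE]
  }
  if (ncol(voxel_matrix) == 0L) {
    stop_restfc(sprintf("All voxels of seed '%s' are masked out.", seed_name))
  }
  centered <- scale(voxel_matrix, center = TRUE, scale = FALSE)
  if (ncol(centered) == 1L) {
    u <- as.numeric(centered)
  } else {
    u <- svd(centered, nu = 1L, nv = 0L)$u[, 1L]
  }
  s <- stats::sd(u)
  if (s < .Machine$double.eps) {
    stop_restfc(sprintf("Seed '%s' has a constant time course.", seed_name))
  }
  u <- (u - mean(u)) / s
  ref <- rowMeans(centered)
  if (sum(u * ref) < 0) u <- -u
  u
}
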
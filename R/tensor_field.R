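# White-matter direction from a diffusion tensor volume: per-voxel
# eigendecomposition, fractional anisotropy, and validity masking.

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clipped to
#' `[0, 1]`.  All-zero eigenvalue triples yield `NA` (no meaningful
#' anisotropy).
#'
#' @param eigenvalues numeric vector of length 3, or an n x 3 matrix of
#'   eigenvalue triples.
#' @return FA value(s) in `[0, 1]` (`NA` where all three eigenvalues are 0).
#' @export
fractional_anisotropy <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, 1)
  if (ncol(ev) != 3L)
    stop_growthtrack("growthtrack_bad_shape",
                     "eigenvalues must come in triples")
  m <- rowMeans(ev)
  dev2 <- rowSums((ev - m)^2)
  nrm2 <- rowSums(ev^2)
  fa <- sqrt(pmax(0, 1.5 * dev2 / nrm2))
  fa <- pmin(pmax(fa, 0), 1)
  fa[nrm2 == 0] <- NA_real_
  if (is.matrix(eigenvalues)) fa else fa[[1]]
}

#' Principal diffusion direction map
#'
#' Computes, per voxel, the unit eigenvector of the largest eigenvalue of
#' the symmetric diffusion tensor, the fractional anisotropy, and a validity
#' flag.  A voxel is valid when (a) the largest eigenvalue is strictly
#' separated from the second (relative gap above `gap_tol`), (b) the tensor
#' is positive semi-definite within tolerance, and (c) `fa >= fa_min`.
#' Degenerate voxels are flagged invalid and counted, never raised as
#' errors.  In `diagonal_only` mode the direction is the coordinate axis of
#' the largest diagonal entry (the diagonal alone cannot encode off-axis
#' directions).
#'
#' Directions are sign-ambiguous; downstream angle computations use the
#' absolute dot product, so the sign never matters.
#'
#' @param tensors a [tensor_volume].
#' @param fa_min fractional-anisotropy gate in `[0, 1]`; the default 0
#'   applies no white-matter restriction.
#' @param gap_tol relative eigenvalue-gap tolerance for direction validity.
#' @return A `direction_field`: list with 4D `direction` (unit vectors,
#'   world frame), 3D logical `valid`, 3D `fa`, the `affine`, and an
#'   `exclusions` tally.
#' @export
principal_direction_map <- function(tensors, fa_min = 0, gap_tol = 1e-6) {
  if (!inherits(tensors, "tensor_volume"))
    stop_growthtrack("growthtrack_bad_type", "tensors must be a tensor_volume")
  if (!is.numeric(fa_min) || fa_min < 0 || fa_min > 1)
    stop_growthtrack("growthtrack_bad_param", "fa_min must lie in [0, 1]")
  shape <- vol_shape(tensors)
  nvox <- prod(shape)
  tm <- matrix(tensors$data, nvox, 6L)

  if (tensors$diagonal_only) {
    dg <- tm[, c(1L, 4L, 6L), drop = FALSE]
    ord <- max.col(dg, ties.method = "first")
    vec <- matrix(0, nvox, 3L)
    vec[cbind(seq_len(nvox), ord)] <- 1
    sorted <- t(apply(dg, 1L, sort, decreasing = TRUE))
    l1 <- sorted[, 1L]; l2 <- sorted[, 2L]; l3 <- sorted[, 3L]
  } else {
    eig <- cpp_eig3_principal(tm)
    l1 <- eig$values[, 1L]; l2 <- eig$values[, 2L]; l3 <- eig$values[, 3L]
    vec <- eig$vector
  }

  scale <- pmax(abs(l1), abs(l3))
  gap_ok <- scale > 0 & (l1 - l2) > gap_tol * scale
  psd_ok <- l3 >= -1e-9 * pmax(scale, 1e-300)
  fa <- fractional_anisotropy(cbind(l1, l2, l3))
  fa_ok <- !is.na(fa) & fa >= fa_min
  vec_ok <- !is.na(vec[, 1L])
  valid <- gap_ok & psd_ok & fa_ok & vec_ok

  vec[!valid, ] <- NA_real_
  fa[is.na(fa)] <- 0

  exclusions <- c(
    eigen_gap = sum(!gap_ok),
    not_psd = sum(gap_ok & !psd_ok),
    below_fa_min = sum(gap_ok & psd_ok & !fa_ok),
    degenerate_vector = sum(gap_ok & psd_ok & fa_ok & !vec_ok)
  )

  structure(list(
    direction = array(vec, c(shape, 3L)),
    valid = array(valid, shape),
    fa = array(fa, shape),
    affine = tensors$affine,
    exclusions = exclusions
  ), class = "direction_field")
}

#' @export
print.direction_field <- function(x, ...) {
  cat(sprintf("<direction_field> %s voxels, %d valid (%.1f%%)\n",
              paste(dim(x$valid), collapse = "x"), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Persist a direction field as NIfTI volumes
#'
#' Writes the vector map, the validity mask and the FA map next to each
#' other (suffixes `_dir`, `_valid`, `_fa`).
#'
#' @param dirs a `direction_field`.
#' @param prefix output path prefix (no extension).
#' @export
write_direction_field <- function(dirs, prefix) {
  vec <- dirs$direction
  vec[is.na(vec)] <- 0
  write_volume(vector_volume(vec, dirs$affine),
               paste0(prefix, "_dir.nii.gz"))
  write_volume(mask_volume(array(as.double(dirs$valid), dim(dirs$valid)),
                           dirs$affine),
               paste0(prefix, "_valid.nii.gz"))
  write_volume(volume_image(dirs$fa, dirs$affine),
               paste0(prefix, "_fa.nii.gz"))
  invisible(prefix)
}

# nearest-neighbour resampling of a direction field onto a reference grid
# (unit vectors cannot be linearly interpolated under sign ambiguity)
resample_direction_field <- function(dirs, reference) {
  if (all(dim(dirs$valid) == vol_shape(reference)) &&
      max(abs(dirs$affine - reference$affine)) <= 1e-6) {
    return(dirs)
  }
  shape <- vol_shape(reference)
  pts <- voxel_centers_world(shape, reference$affine)
  vox <- world_to_voxel(pts, dirs$affine)
  comp <- lapply(1:3, function(c)
    cpp_sample_points(dirs$direction[, , , c], dim(dirs$valid), vox,
                      1L, NA_real_, 0.5))
  valid <- cpp_sample_points(array(as.double(dirs$valid), dim(dirs$valid)),
                             dim(dirs$valid), vox, 1L, 0, 0.5) > 0.5
  fa <- cpp_sample_points(dirs$fa, dim(dirs$valid), vox, 1L, 0, 0.5)
  structure(list(
    direction = array(unlist(comp), c(shape, 3L)),
    valid = array(valid & !is.na(comp[[1]]), shape),
    fa = array(fa, shape),
    affine = reference$affine,
    exclusions = dirs$exclusions
  ), class = "direction_field")
}
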
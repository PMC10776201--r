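#' @useDynLib growthtrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var qt pt pf pnorm rnorm runif optim setNames
#' @importFrom utils read.csv write.csv modifyList packageVersion
NULL

# ---------------------------------------------------------------------------
# Lightweight S3 containers.  All volumes carry a 4x4 voxel-to-world affine
# (mm, RAS+) mapping 0-based voxel indices to world coordinates.
# ---------------------------------------------------------------------------

stop_growthtrack <- function(class, msg, ...) {
  stop(structure(class = c(class, "growthtrack_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_affine <- function(affine, what = "volume") {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine))) {
    stop_growthtrack("growthtrack_bad_affine",
                     "%s affine must be a finite 4x4 matrix", what)
  }
  if (abs(det(affine[1:3, 1:3, drop = FALSE])) < .Machine$double.eps * 100) {
    stop_growthtrack("growthtrack_bad_affine",
                     "%s affine is not invertible", what)
  }
  affine[4, ] <- c(0, 0, 0, 1)
  unname(affine)
}

#' Scalar image volume
#'
#' A 3D scalar grid together with a 4x4 voxel-to-world affine (mm).  Voxel
#' indices are 0-based in the affine convention (NIfTI style): the world
#' position of array element `[i, j, k]` is `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop_growthtrack("growthtrack_bad_shape", "volume data must be 3D")
  affine <- check_affine(affine, "volume")
  structure(list(data = array(as.double(data), dim(data)), affine = affine),
            class = "volume_image")
}

#' Binary mask volume
#'
#' Values are stored as 0/1; anything above 0.5 is foreground.
#'
#' @inheritParams volume_image
#' @return An object of class `mask_volume` (also a `volume_image`).
#' @export
mask_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop_growthtrack("growthtrack_bad_shape", "mask data must be 3D")
  affine <- check_affine(affine, "mask")
  bin <- array(as.double(data > 0.5), dim(data))
  structure(list(data = bin, affine = affine),
            class = c("mask_volume", "volume_image"))
}

#' Per-voxel 3-vector volume
#'
#' Stored as a 4D array with the vector component along the 4th axis;
#' components are in world millimetres.
#'
#' @param data numeric 4D array with last extent 3.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @export
vector_volume <- function(data, affine = diag(4)) {
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop_growthtrack("growthtrack_bad_shape",
                     "vector volume must be 4D with last extent 3")
  affine <- check_affine(affine, "vector volume")
  structure(list(data = array(as.double(data), d), affine = affine),
            class = "vector_volume")
}

#' Deformation field volume
#'
#' A [vector_volume] whose vectors are displacements in world millimetres on
#' the reference grid: the growth vector of the material point observed at a
#' voxel (pointing outward for expansion).
#'
#' @inheritParams vector_volume
#' @export
deformation_volume <- function(data, affine = diag(4)) {
  v <- vector_volume(data, affine)
  class(v) <- c("deformation_volume", class(v))
  v
}

#' Diffusion tensor volume
#'
#' Per-voxel symmetric 3x3 tensors stored as six component grids in canonical
#' order (xx, xy, xz, yy, yz, zz), units mm^2/s.  When `diagonal_only` the
#' off-diagonal slices are zero and only the diagonal entries are meaningful.
#'
#' @param data numeric 4D array with last extent 6 (or 3 for diagonal-only
#'   input, which is padded with zero off-diagonals).
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param diagonal_only logical flag.
#' @export
tensor_volume <- function(data, affine = diag(4), diagonal_only = FALSE) {
  d <- dim(data)
  if (length(d) != 4L || !(d[4] %in% c(3L, 6L)))
    stop_growthtrack("growthtrack_bad_shape",
                     "tensor volume must be 4D with last extent 3 or 6")
  affine <- check_affine(affine, "tensor volume")
  if (d[4] == 3L) {
    full <- array(0, c(d[1:3], 6L))
    full[, , , 1] <- data[, , , 1]  # xx
    full[, , , 4] <- data[, , , 2]  # yy
    full[, , , 6] <- data[, , , 3]  # zz
    data <- full
    diagonal_only <- TRUE
  }
  structure(list(data = array(as.double(data), dim(data)), affine = affine,
                 diagonal_only = isTRUE(diagonal_only)),
            class = "tensor_volume")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(signif(voxel_spacing(x), 4), collapse = "x")))
  invisible(x)
}

#' @export
print.vector_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels x %d components\n", class(x)[1],
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4]))
  invisible(x)
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %s voxels%s\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              if (x$diagonal_only) " (diagonal only)" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Grid helpers
# ---------------------------------------------------------------------------

vol_shape <- function(x) dim(x$data)[1:3]

voxel_spacing <- function(x) {
  A <- if (is.matrix(x)) x else x$affine
  sqrt(colSums(A[1:3, 1:3]^2))
}

voxel_volume_mm3 <- function(x) {
  A <- if (is.matrix(x)) x else x$affine
  abs(det(A[1:3, 1:3]))
}

same_grid <- function(a, b, tol = 1e-6) {
  all(vol_shape(a) == vol_shape(b)) && max(abs(a$affine - b$affine)) <= tol
}

require_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop_growthtrack("growthtrack_grid_mismatch",
                     "%s are not on the same grid", what)
  invisible(TRUE)
}

# world coordinates (n x 3, mm) of every voxel centre, x fastest
voxel_centers_world <- function(shape, affine) {
  idx <- cbind(
    rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

# map world coordinates (n x 3) to 0-based voxel coordinates
world_to_voxel <- function(pts, affine) {
  inv <- solve(affine)
  sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)
}

# default affine: isotropic spacing with the world origin at the grid centre
center_affine <- function(shape, spacing = 1) {
  spacing <- rep(spacing, length.out = 3)
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- -(shape - 1) * spacing / 2
  A
}

#' 4x4 world-to-world affine transform
#'
#' @param matrix a 4x4 homogeneous matrix (mm) with bottom row (0,0,0,1).
#' @export
affine_transform <- function(matrix = diag(4)) {
  m <- check_affine(matrix, "transform")
  structure(list(matrix = m), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}
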
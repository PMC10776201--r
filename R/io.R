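# NIfTI and tabular input/output.  All volumes are NIfTI-1; geometry is taken
# from the sform when present (qform otherwise), so round trips are exact.

nifti_affine <- function(img, path) {
  A <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(A) <- list(dim = dim(A))
  tryCatch(check_affine(A, sprintf("'%s'", path)),
           growthtrack_bad_affine = function(e) {
             stop_growthtrack("growthtrack_bad_affine",
                              "non-invertible affine in '%s'", path)
           })
}

#' Read a NIfTI volume
#'
#' Reads a 3D scalar or mask volume, or a 4D stack with last extent 3
#' (vector field) or 6 (tensor components), and returns the matching
#' container.  Masks are binarized at > 0.5 on read, which makes reading
#' robust to interpolation residue in stored masks.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param type one of `"auto"`, `"image"`, `"mask"`, `"vector"`, `"tensor"`,
#'   `"deformation"`.  With `"auto"`, 3D files become [volume_image] and 4D
#'   files become [vector_volume] or [tensor_volume] by their last extent.
#' @return A [volume_image], [mask_volume], [vector_volume],
#'   [deformation_volume] or [tensor_volume].
#' @export
read_volume <- function(path, type = c("auto", "image", "mask", "vector",
                                       "tensor", "deformation")) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop_growthtrack("growthtrack_missing_file", "file not found: '%s'", path)
  img <- RNifti::readNifti(path)
  A <- nifti_affine(img, path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3L) {
    if (type %in% c("vector", "tensor", "deformation"))
      stop_growthtrack("growthtrack_bad_shape",
                       "'%s' is 3D but type '%s' was requested", path, type)
    if (type == "mask") return(mask_volume(arr, A))
    return(volume_image(arr, A))
  }
  if (nd == 4L) {
    k <- dim(arr)[4]
    if (type == "mask" || type == "image")
      stop_growthtrack("growthtrack_bad_shape",
                       "'%s' is 4D but a 3D %s was requested", path, type)
    if (k == 3L && type %in% c("auto", "vector"))
      return(vector_volume(arr, A))
    if (k == 3L && type == "deformation")
      return(deformation_volume(arr, A))
    if (k == 6L && type %in% c("auto", "tensor"))
      return(tensor_volume(arr, A))
    if (k == 3L && type == "tensor")
      return(tensor_volume(arr, A))
    stop_growthtrack("growthtrack_bad_shape",
                     "'%s' has unsupported 4th extent %d", path, k)
  }
  stop_growthtrack("growthtrack_bad_shape",
                   "'%s' has unsupported dimensionality %d", path, nd)
}

#' Write a volume to NIfTI-1
#'
#' Vector/tensor stacks are written as 4D with components along the 4th
#' axis; the component order is recorded in the header description field.
#'
#' @param vol a volume container.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  desc <- switch(class(vol)[1],
    tensor_volume = "tensor components xx,xy,xz,yy,yz,zz",
    vector_volume = "vector components x,y,z (world mm)",
    deformation_volume = "displacement x,y,z (world mm)",
    "")
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  if (nzchar(desc)) img$descrip <- desc
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble a tensor volume from component files
#'
#' Takes six component volumes in canonical order (xx, xy, xz, yy, yz, zz)
#' or three diagonal components (xx, yy, zz), which implies
#' `diagonal_only`.  All components must share grid and affine.
#'
#' @param paths character vector of 6 or 3 NIfTI paths.
#' @return A [tensor_volume].
#' @export
read_tensor_components <- function(paths) {
  if (!length(paths) %in% c(3L, 6L))
    stop_growthtrack("growthtrack_bad_shape",
                     "expected 6 or 3 component paths, got %d", length(paths))
  comps <- lapply(paths, read_volume, type = "image")
  ref <- comps[[1]]
  for (i in seq_along(comps)[-1]) {
    if (!same_grid(ref, comps[[i]]))
      stop_growthtrack("growthtrack_grid_mismatch",
                       "component '%s' is not on the grid of '%s'",
                       paths[i], paths[1])
  }
  arr <- array(0, c(vol_shape(ref), length(paths)))
  for (i in seq_along(comps)) arr[, , , i] <- comps[[i]]$data
  tensor_volume(arr, ref$affine, diagonal_only = length(paths) == 3L)
}

results_columns <- function() {
  c("patient_id", "v1_mm3", "v2_mm3", "interval_days", "growth_rate",
    paste0("bin", 1:9), "parallel_fraction", "perpendicular_fraction",
    "n_voxels", "n_excluded_degenerate", "mgmt")
}

#' Write per-patient results to CSV
#'
#' One row per patient: volumes at both timepoints (mm^3), scan interval,
#' growth rate (%/day), the nine 10-degree bin fractions, the parallel and
#' perpendicular summary fractions, and MGMT status.  Numbers are written
#' with enough precision that re-reading reproduces them to at least 10
#' significant digits.
#'
#' @param records a list of `patient_result` objects (see
#'   [quantify_patient]).
#' @param path output CSV path.
#' @export
write_results_table <- function(records, path) {
  if (length(records) == 0)
    stop_growthtrack("growthtrack_empty_records",
                     "no patient records to write")
  rows <- lapply(records, function(r) {
    h <- r$histogram
    data.frame(patient_id = r$patient_id, v1_mm3 = r$v1, v2_mm3 = r$v2,
               interval_days = r$interval_days, growth_rate = r$growth_rate,
               t(setNames(h$bin_fractions, paste0("bin", 1:9))),
               parallel_fraction = h$parallel_fraction,
               perpendicular_fraction = h$perpendicular_fraction,
               n_voxels = h$n_voxels,
               n_excluded_degenerate = h$n_excluded_degenerate,
               mgmt = r$mgmt, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[, results_columns()]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.15g", df[[j]])
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    stop_growthtrack("growthtrack_unwritable",
                                     "cannot write '%s'", path))
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-patient results table written by [write_results_table]
#' @param path CSV path.
#' @return A data frame with one row per patient.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    stop_growthtrack("growthtrack_missing_file", "file not found: '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(results_columns(), names(df))
  if (length(missing))
    stop_growthtrack("growthtrack_bad_table",
                     "results table '%s' lacks columns: %s", path,
                     paste(missing, collapse = ", "))
  df
}
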
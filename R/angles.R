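# Quantification core: select growth voxels, compute voxel-wise angles
# between growth vectors and white-matter directions, bin into nine
# 10-degree bins, and classify parallel / perpendicular fractions.

#' Angle between a growth vector and a fiber direction
#'
#' `acos(|g . w| / (|g| |w|))` in degrees, in `[0, 90]`.  Fiber directions
#' are sign-ambiguous, so the absolute dot product makes the angle invariant
#' to the sign (and scale) of either argument.
#'
#' @param g growth vector(s): length-3 vector or n x 3 matrix.
#' @param w direction vector(s), same shape.
#' @return Angle(s) in degrees.
#' @export
angle_between <- function(g, w) {
  gm <- if (is.matrix(g)) g else matrix(g, 1)
  wm <- if (is.matrix(w)) w else matrix(w, 1)
  if (ncol(gm) != 3L || ncol(wm) != 3L || nrow(gm) != nrow(wm))
    stop_growthtrack("growthtrack_bad_shape",
                     "g and w must be 3-vectors or matching n x 3 matrices")
  ng <- sqrt(rowSums(gm^2))
  nw <- sqrt(rowSums(wm^2))
  if (any(ng == 0) || any(nw == 0))
    stop_growthtrack("growthtrack_zero_vector",
                     "zero-length vector in angle computation")
  cosang <- pmin(1, abs(rowSums(gm * wm)) / (ng * nw))
  ang <- acos(cosang) * 180 / pi
  if (is.matrix(g)) ang else ang[[1]]
}

#' Select the voxels entering the growth-direction analysis
#'
#' Included voxels are the union of the two tumor masks, restricted to
#' displacements with magnitude above `eps_mm` (a numerically-zero
#' displacement has no meaningful direction) and to voxels with a valid
#' fiber direction.  Excluded voxels are tallied per reason.
#'
#' @param def a [deformation_volume] on the analysis grid.
#' @param mask_t1,mask_t2 [mask_volume]s on the same grid.
#' @param dirs a `direction_field` (resampled to the grid if needed,
#'   nearest-neighbour).
#' @param eps_mm displacement magnitude gate in mm (default 0.1).
#' @return A `growth_voxel_set`: voxel indices, growth vectors (mm),
#'   matched unit directions, magnitudes and exclusion tallies.
#' @export
select_growth_voxels <- function(def, mask_t1, mask_t2, dirs, eps_mm = 0.1) {
  require_same_grid(def, mask_t1, "deformation and t1 mask")
  require_same_grid(def, mask_t2, "deformation and t2 mask")
  dirs <- resample_direction_field(dirs, def)
  shape <- vol_shape(def)
  nvox <- prod(shape)
  u <- matrix(def$data, nvox, 3L)
  union <- as.vector(mask_t1$data > 0.5 | mask_t2$data > 0.5)
  mag <- sqrt(rowSums(u^2))
  above <- mag > eps_mm
  valid <- as.vector(dirs$valid)
  keep <- union & above & valid
  idx <- which(keep)
  dmat <- matrix(dirs$direction, nvox, 3L)
  structure(list(
    idx = idx,
    vectors = u[idx, , drop = FALSE],
    directions = dmat[idx, , drop = FALSE],
    magnitudes = mag[idx],
    n_union = sum(union),
    exclusions = c(below_magnitude = sum(union & !above),
                   invalid_direction = sum(union & above & !valid))
  ), class = "growth_voxel_set")
}

#' Construct a growth voxel set from raw vectors
#'
#' Mainly for simulation studies (e.g. sampling growth directions from a
#' known distribution against a fixed fiber direction) where the voxel grid
#' is irrelevant.
#'
#' @param vectors n x 3 matrix of growth vectors (mm).
#' @param directions n x 3 matrix of matched fiber directions.
#' @param magnitudes optional vector of weights; defaults to the vector
#'   norms.
#' @export
growth_voxel_set <- function(vectors, directions, magnitudes = NULL) {
  vectors <- as.matrix(vectors)
  directions <- as.matrix(directions)
  if (ncol(vectors) != 3L || !all(dim(vectors) == dim(directions)))
    stop_growthtrack("growthtrack_bad_shape",
                     "vectors and directions must be matching n x 3")
  structure(list(
    idx = seq_len(nrow(vectors)),
    vectors = vectors, directions = directions,
    magnitudes = magnitudes %||% sqrt(rowSums(vectors^2)),
    n_union = nrow(vectors),
    exclusions = c(below_magnitude = 0L, invalid_direction = 0L)
  ), class = "growth_voxel_set")
}

#' @export
print.growth_voxel_set <- function(x, ...) {
  cat(sprintf("<growth_voxel_set> %d voxels (of %d in union; %d low-magnitude, %d invalid-direction)\n",
              length(x$idx), x$n_union, x$exclusions[["below_magnitude"]],
              x$exclusions[["invalid_direction"]]))
  invisible(x)
}

#' Construct an angle histogram
#'
#' @param bin_fractions nine fractions over the bins
#'   `[0,10), [10,20), ..., [80,90]`.
#' @param n_voxels number of included voxels.
#' @param n_excluded_degenerate number of union voxels excluded.
#' @param parallel_max,perpendicular_min classification thresholds in
#'   degrees (defaults 20 and 70): parallel is `[0, parallel_max)`,
#'   perpendicular is `[perpendicular_min, 90]`.
#' @export
angle_histogram <- function(bin_fractions, n_voxels = 0L,
                            n_excluded_degenerate = 0L,
                            parallel_max = 20, perpendicular_min = 70) {
  bin_fractions <- as.double(bin_fractions)
  if (length(bin_fractions) != 9L)
    stop_growthtrack("growthtrack_bad_shape", "expected nine bin fractions")
  if (n_voxels > 0 && abs(sum(bin_fractions) - 1) > 1e-9)
    stop_growthtrack("growthtrack_bad_param",
                     "bin fractions must sum to 1")
  edges <- seq(0, 90, by = 10)
  par_bins <- which(edges[-10] < parallel_max)
  perp_bins <- which(edges[-1] > perpendicular_min)
  structure(list(
    bin_fractions = bin_fractions,
    n_voxels = as.integer(n_voxels),
    n_excluded_degenerate = as.integer(n_excluded_degenerate),
    parallel_fraction = sum(bin_fractions[par_bins]),
    perpendicular_fraction = sum(bin_fractions[perp_bins])
  ), class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("<angle_histogram> n = %d voxels\n", x$n_voxels))
  lab <- sprintf("%d-%d", seq(0, 80, 10), seq(10, 90, 10))
  cat(paste(sprintf("  %s: %5.1f%%", lab, 100 * x$bin_fractions),
            collapse = "\n"), "\n")
  cat(sprintf("  parallel (0-20): %.1f%%  perpendicular (70-90): %.1f%%\n",
              100 * x$parallel_fraction, 100 * x$perpendicular_fraction))
  invisible(x)
}

#' Bin growth angles into nine 10-degree bins
#'
#' Each included voxel contributes weight 1 (`"count"`) or its displacement
#' magnitude (`"magnitude"`) to the bin containing its angle.  Bins are
#' half-open `[a, a+10)` except the last, `[80, 90]`; an angle of exactly
#' 20 degrees is therefore not parallel, and exactly 70 degrees falls in the
#' 70-80 bin.
#'
#' @param voxels a `growth_voxel_set` from [select_growth_voxels].
#' @param weighting `"count"` (default: one vote per voxel) or
#'   `"magnitude"`.
#' @param parallel_max,perpendicular_min classification thresholds
#'   (degrees).
#' @return An [angle_histogram].
#' @export
bin_histogram <- function(voxels, weighting = c("count", "magnitude"),
                          parallel_max = 20, perpendicular_min = 70) {
  weighting <- match.arg(weighting)
  if (length(voxels$idx) == 0)
    stop_growthtrack("growthtrack_empty_voxelset",
                     "no voxels to bin: report this patient as non-evaluable")
  ang <- angle_between(voxels$vectors, voxels$directions)
  bins <- pmin(floor(ang / 10) + 1L, 9L)  # angle 90 joins the [80, 90] bin
  w <- if (weighting == "count") rep(1, length(bins)) else voxels$magnitudes
  tot <- vapply(1:9, function(b) sum(w[bins == b]), 0.0)
  angle_histogram(tot / sum(tot), n_voxels = length(bins),
                  n_excluded_degenerate = sum(voxels$exclusions),
                  parallel_max = parallel_max,
                  perpendicular_min = perpendicular_min)
}

#' Quantify one patient
#'
#' Composes voxel selection, angle computation and histogram binning, and
#' attaches volumes (voxel count times voxel volume), the scan interval and
#' the growth rate.
#'
#' @param mask_t1,mask_t2 tumor masks on the analysis grid.
#' @param def the growth [deformation_volume].
#' @param dirs the fiber `direction_field`.
#' @param patient_id identifier string.
#' @param interval_days days between the two scans (> 0).
#' @param mgmt `"methylated"`, `"unmethylated"` or `"unknown"`.
#' @param eps_mm displacement magnitude gate (mm).
#' @param weighting `"count"` or `"magnitude"`.
#' @param parallel_max,perpendicular_min classification thresholds
#'   (degrees).
#' @param rate one of `"specific"` (`100 * ln(v2/v1) / days`, default) or
#'   `"linear"` (`100 * (v2 - v1) / (v1 * days)`).
#' @return A `patient_result`.
#' @export
quantify_patient <- function(mask_t1, mask_t2, def, dirs,
                             patient_id = "patient", interval_days = 1,
                             mgmt = "unknown", eps_mm = 0.1,
                             weighting = "count", parallel_max = 20,
                             perpendicular_min = 70,
                             rate = c("specific", "linear")) {
  rate <- match.arg(rate)
  sel <- select_growth_voxels(def, mask_t1, mask_t2, dirs, eps_mm = eps_mm)
  hist <- bin_histogram(sel, weighting = weighting,
                        parallel_max = parallel_max,
                        perpendicular_min = perpendicular_min)
  vv <- voxel_volume_mm3(mask_t1)
  v1 <- sum(mask_t1$data) * vv
  v2 <- sum(mask_t2$data) * vv
  structure(list(
    patient_id = patient_id, v1 = v1, v2 = v2,
    interval_days = interval_days,
    growth_rate = growth_rate(v1, v2, interval_days, type = rate),
    histogram = hist, mgmt = mgmt,
    exclusions = sel$exclusions
  ), class = "patient_result")
}

#' @export
print.patient_result <- function(x, ...) {
  cat(sprintf("<patient_result> %s: v1 %.0f mm^3 -> v2 %.0f mm^3 over %d d (%.2f %%/day)\n",
              x$patient_id, x$v1, x$v2, x$interval_days, x$growth_rate))
  print(x$histogram)
  invisible(x)
}
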
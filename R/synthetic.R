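# Synthetic phantom generator: fiber/tensor templates, two-timepoint tumor
# masks grown with a controllable angular relationship to the fibers, the
# analytic ground-truth deformation, and whole cohorts with metadata.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_growthtrack("growthtrack_bad_param",
                               "direction vector must be nonzero")
  v / n
}

#' Fiber pattern specification
#'
#' Describes the white-matter orientation field of a synthetic tensor
#' template and the anisotropy of its tensors.
#'
#' @param kind `"uniform"` (constant direction), `"radial"` (directions
#'   pointing away from `center`) or `"curved"` (direction rotating around
#'   `axis` with position).
#' @param direction unit 3-vector for `"uniform"`.
#' @param center world-mm triple for `"radial"`.
#' @param axis base direction for `"curved"`.
#' @param curvature rotation rate (radians per mm) for `"curved"`.
#' @param fa_target fractional anisotropy of every generated tensor, in
#'   `[0, 1)`.
#' @param mean_diffusivity mean diffusivity in mm^2/s (default 7e-4, a
#'   typical white-matter value).
#' @export
fiber_pattern <- function(kind = c("uniform", "radial", "curved"),
                          direction = c(1, 0, 0), center = c(0, 0, 0),
                          axis = c(1, 0, 0), curvature = 0.02,
                          fa_target = 0.5, mean_diffusivity = 7e-4) {
  kind <- match.arg(kind)
  if (!is.numeric(fa_target) || fa_target < 0 || fa_target >= 1)
    stop_growthtrack("growthtrack_bad_param", "fa_target must lie in [0, 1)")
  if (mean_diffusivity <= 0)
    stop_growthtrack("growthtrack_bad_param", "mean_diffusivity must be > 0")
  structure(list(kind = kind, direction = normalize3(direction),
                 center = as.double(center), axis = normalize3(axis),
                 curvature = curvature, fa_target = fa_target,
                 mean_diffusivity = mean_diffusivity),
            class = "fiber_pattern")
}

# prolate tensor with principal direction e, exact FA f and mean diffusivity m:
# eigenvalues (a, b, b) with a/b solving f^2 = (r-1)^2 / (r^2 + 2)
prolate_eigenvalues <- function(f, m) {
  if (f == 0) return(c(m, m))
  r <- (1 + sqrt(1 - (1 - f^2) * (1 - 2 * f^2))) / (1 - f^2)
  b <- 3 * m / (r + 2)
  c(a = r * b, b = b)
}

#' Generate a synthetic fiber tensor template
#'
#' Every voxel receives a symmetric positive-definite tensor whose principal
#' eigenvector follows the pattern's direction field and whose fractional
#' anisotropy equals `fa_target` exactly (to floating point).  Voxels where
#' the pattern direction is undefined (e.g. the centre of a radial field)
#' get an isotropic tensor, which downstream validity masking flags.
#'
#' @param shape grid size, integer triple.
#' @param pattern a [fiber_pattern].
#' @param affine voxel-to-world matrix; default centres the grid at the
#'   world origin with 1 mm spacing.
#' @return A [tensor_volume].
#' @export
generate_fiber_field <- function(shape, pattern,
                                 affine = center_affine(shape)) {
  stopifnot(inherits(pattern, "fiber_pattern"))
  shape <- as.integer(shape)
  pts <- voxel_centers_world(shape, affine)
  n <- nrow(pts)
  dirs <- switch(pattern$kind,
    uniform = matrix(pattern$direction, n, 3, byrow = TRUE),
    radial = {
      d <- sweep(pts, 2, pattern$center, `-`)
      nn <- sqrt(rowSums(d^2))
      ok <- nn > 0
      d[ok, ] <- d[ok, ] / nn[ok]
      d[!ok, ] <- NA_real_
      d
    },
    curved = {
      # direction rotates around `axis` at `curvature` rad/mm along axis
      a <- pattern$axis
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- normalize3(pracma_cross(a, ref))
      e2 <- pracma_cross(a, e1)
      th <- pattern$curvature * as.vector(pts %*% a)
      outer(cos(th), e1) + outer(sin(th), e2)
    })
  ab <- prolate_eigenvalues(pattern$fa_target, pattern$mean_diffusivity)
  a <- ab[[1]]; b <- ab[[2]]
  comp <- matrix(0, n, 6)
  und <- is.na(dirs[, 1])
  d1 <- dirs[, 1]; d2 <- dirs[, 2]; d3 <- dirs[, 3]
  comp[, 1] <- (a - b) * d1 * d1 + b
  comp[, 2] <- (a - b) * d1 * d2
  comp[, 3] <- (a - b) * d1 * d3
  comp[, 4] <- (a - b) * d2 * d2 + b
  comp[, 5] <- (a - b) * d2 * d3
  comp[, 6] <- (a - b) * d3 * d3 + b
  if (any(und)) {
    m <- pattern$mean_diffusivity
    comp[und, ] <- rep(c(m, 0, 0, m, 0, m), each = sum(und))
  }
  tensor_volume(array(comp, c(shape, 6L)), affine)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Tumor growth specification
#'
#' @param center tumor centre in world mm.
#' @param r1 baseline radius in mm (> 0).
#' @param mode `"isotropic"`, `"along_fiber"`, `"fixed_direction"` or
#'   `"random_isotropic_vectors"` (a spherical expansion whose analytic
#'   growth vectors are radial, i.e. isotropically distributed — the
#'   direction-free null).
#' @param factor expansion factor for the isotropic modes (>= 1).
#' @param factor_parallel,factor_perpendicular semi-axis expansion factors
#'   for the ellipsoidal modes; `factor_parallel >= factor_perpendicular >= 1`.
#' @param axis expansion axis for `"fixed_direction"` (unit vector; for
#'   `"along_fiber"` the axis is the fiber direction at the tumor centre).
#' @param seed integer recorded with the spec (the simulator itself is
#'   deterministic; randomness lives in cohort generation).
#' @export
growth_spec <- function(center = c(0, 0, 0), r1 = 6,
                        mode = c("isotropic", "along_fiber",
                                 "fixed_direction",
                                 "random_isotropic_vectors"),
                        factor = 1.4, factor_parallel = 1.5,
                        factor_perpendicular = 1.1, axis = c(1, 0, 0),
                        seed = NA_integer_) {
  mode <- match.arg(mode)
  if (r1 <= 0) stop_growthtrack("growthtrack_bad_param", "r1 must be > 0")
  if (mode %in% c("isotropic", "random_isotropic_vectors")) {
    factor_parallel <- factor_perpendicular <- factor
  }
  if (factor_parallel < 1 || factor_perpendicular < 1)
    stop_growthtrack("growthtrack_bad_param",
                     "expansion factors must be >= 1")
  if (factor_parallel < factor_perpendicular)
    stop_growthtrack("growthtrack_bad_param",
                     "factor_parallel must be >= factor_perpendicular")
  structure(list(center = as.double(center), r1 = r1, mode = mode,
                 factor_parallel = factor_parallel,
                 factor_perpendicular = factor_perpendicular,
                 axis = normalize3(axis), seed = seed),
            class = "growth_spec")
}

#' Simulate two-timepoint tumor masks with analytic ground truth
#'
#' The baseline mask is the sphere of radius `r1`; the follow-up mask is its
#' anisotropic affine expansion `A = fp * P + fperp * (I - P)` (with `P` the
#' projector on the expansion axis), rasterized analytically per voxel
#' centre so the ground truth is exact.  The true deformation is the growth
#' field of that expansion evaluated on the follow-up grid,
#' `w(x) = (I - A^-1)(x - c)` inside the follow-up mask: the displacement of
#' the material point observed at `x`, pointing outward.  For
#' `factor_perpendicular = 1` every growth vector is exactly axis-parallel.
#' The true angle histogram applies the standard voxel selection (union,
#' magnitude gate, valid fiber direction) to this analytic field.
#'
#' @param shape grid size (integer triple).
#' @param spec a [growth_spec].
#' @param fibers optional [tensor_volume] on the same grid; required for
#'   `mode = "along_fiber"` and for the ground-truth histogram.
#' @param affine voxel-to-world matrix.
#' @param eps_mm magnitude gate used for the ground-truth histogram (mm).
#' @return A list with `t1`, `t2` ([mask_volume]s) and `truth` (list with
#'   `true_deformation`, `true_angle_histogram`, `v1`, `v2`, `axis`).
#' @export
simulate_tumor_growth <- function(shape, spec, fibers = NULL,
                                  affine = center_affine(shape),
                                  eps_mm = 0.1) {
  stopifnot(inherits(spec, "growth_spec"))
  shape <- as.integer(shape)
  fp <- spec$factor_parallel
  fq <- spec$factor_perpendicular
  axis <- switch(spec$mode,
    along_fiber = {
      if (is.null(fibers))
        stop_growthtrack("growthtrack_bad_param",
                         "along_fiber mode requires a fiber field")
      dirs <- principal_direction_map(fibers)
      cv <- round(world_to_voxel(matrix(spec$center, 1), fibers$affine)) + 1
      cv <- pmin(pmax(cv, 1), vol_shape(fibers))
      ax <- dirs$direction[cv[1], cv[2], cv[3], ]
      if (any(is.na(ax)))
        stop_growthtrack("growthtrack_bad_param",
                         "no valid fiber direction at the tumor centre")
      ax
    },
    fixed_direction = spec$axis,
    c(1, 0, 0))  # irrelevant for isotropic modes (fp == fq)

  pts <- voxel_centers_world(shape, affine)
  d <- sweep(pts, 2, spec$center, `-`)
  par_comp <- as.vector(d %*% axis)
  perp2 <- rowSums(d^2) - par_comp^2
  r2 <- rowSums(d^2)

  t1_in <- r2 <= spec$r1^2
  t2_in <- (par_comp / (spec$r1 * fp))^2 + perp2 / (spec$r1 * fq)^2 <= 1
  if (!any(t1_in))
    stop_growthtrack("growthtrack_bad_param", "baseline tumor is empty")
  # expanded tumor must fit with margin inside the grid
  lim <- pmin(abs(pts[1, ] - spec$center), abs(pts[nrow(pts), ] - spec$center))
  if (spec$r1 * fp > min(lim))
    stop_growthtrack("growthtrack_out_of_bounds",
                     "expanded tumor exceeds the grid")

  # growth field of the affine expansion, on the follow-up (t2) support
  w <- d * (1 - 1 / fq)
  if (fp != fq) {
    adj <- ((1 - 1 / fp) - (1 - 1 / fq)) * par_comp
    w <- w + outer(adj, axis)
  }
  w[!t2_in, ] <- 0

  t1 <- mask_volume(array(as.double(t1_in), shape), affine)
  t2 <- mask_volume(array(as.double(t2_in), shape), affine)
  def <- deformation_volume(array(w, c(shape, 3L)), affine)

  hist <- NULL
  if (!is.null(fibers)) {
    dirs <- resample_direction_field(principal_direction_map(fibers), t1)
    sel <- select_growth_voxels(def, t1, t2, dirs, eps_mm = eps_mm)
    hist <- tryCatch(bin_histogram(sel),
                     growthtrack_empty_voxelset = function(e) NULL)
  }
  vv <- voxel_volume_mm3(t1)
  list(t1 = t1, t2 = t2,
       truth = list(true_deformation = def, true_angle_histogram = hist,
                    v1 = sum(t1$data) * vv, v2 = sum(t2$data) * vv,
                    axis = axis, spec = spec))
}

#' Synthetic postcontrast image for a tumor mask
#'
#' A smooth brain-like ellipsoid with mild intensity structure plus a bright
#' tumor; enough contrast for affine registration, with no claim to MR
#' realism.
#'
#' @param mask a [mask_volume] of the tumor.
#' @param seed integer seed for the background texture.
#' @return A [volume_image] on the mask grid.
#' @export
synthetic_t1_image <- function(mask, seed = 1L) {
  shape <- vol_shape(mask)
  pts <- voxel_centers_world(shape, mask$affine)
  half <- (shape - 1) * voxel_spacing(mask) / 2
  brain <- rowSums(sweep(pts, 2, 0.85 * half, `/`)^2) <= 1
  set.seed(seed)
  ph <- runif(6, 0, 2 * pi)
  fr <- matrix(runif(9, 0.05, 0.15), 3)
  tex <- sin(pts %*% fr[, 1] + ph[1]) + cos(pts %*% fr[, 2] + ph[2]) +
    sin(pts %*% fr[, 3] + ph[3])
  img <- ifelse(brain, 60 + 12 * as.vector(tex), 0)
  img[mask$data > 0.5] <- 110
  volume_image(array(img, shape), mask$affine)
}

#' Smooth structured phantom for registration exercises
#'
#' Sum of seeded Gaussian blobs inside an ellipsoidal support; smooth and
#' feature-rich, which gradient-based affine registration needs.
#'
#' @param shape grid size.
#' @param affine voxel-to-world matrix.
#' @param n_blobs number of Gaussian blobs.
#' @param seed RNG seed.
#' @export
make_structured_phantom <- function(shape = c(48, 48, 48),
                                    affine = center_affine(shape),
                                    n_blobs = 12, seed = 42L) {
  set.seed(seed)
  pts <- voxel_centers_world(shape, affine)
  half <- (shape - 1) * voxel_spacing(list(affine = affine)) / 2
  img <- numeric(nrow(pts))
  for (i in seq_len(n_blobs)) {
    c0 <- runif(3, -0.5, 0.5) * half
    s0 <- runif(1, 3, 8)
    a0 <- runif(1, 20, 100)
    img <- img + a0 * exp(-rowSums(sweep(pts, 2, c0, `-`)^2) / (2 * s0^2))
  }
  supp <- rowSums(sweep(pts, 2, 0.9 * half, `/`)^2) <= 1
  img[!supp] <- 0
  volume_image(array(img, shape), affine)
}

# ---------------------------------------------------------------------------
# Cohorts
# ---------------------------------------------------------------------------

mgmt_levels <- c("methylated", "unmethylated", "unknown")
# label proportions of the reference clinical cohort (35/16/27 of 78)
mgmt_probs <- c(35, 16, 27) / 78

#' Simulate a cohort of synthetic patients in memory
#'
#' Each patient receives a baseline sphere and an expanded follow-up mask.
#' A fraction `bias` of patients grows along the local fiber direction
#' (ellipsoidal, `factor_parallel`/`factor_perpendicular`); the rest grow
#' spherically (`random_isotropic_vectors`, the direction-free null with a
#' volume-matched factor).  All randomness flows from `seed + patient index`
#' so cohorts are reproducible patient by patient.
#'
#' @param n_patients number of patients (>= 2).
#' @param bias fraction of along-fiber patients in `[0, 1]`.
#' @param seed integer seed.
#' @param shape grid size (default 64^3 at 1 mm).
#' @param pattern [fiber_pattern] of the shared template.
#' @param ranges list of simulation ranges: `r1` (mm), `center_jitter` (mm),
#'   `factor_parallel`, `factor_perpendicular`, `interval_days`
#'   (uniform integer, default 4 to 97 days).
#' @return list with `template` ([tensor_volume]), `patients` (list of
#'   per-patient lists: `id`, `t1`, `t2`, `truth`, `interval_days`, `mgmt`,
#'   `mode`) and `metadata` (data frame).
#' @export
simulate_cohort <- function(n_patients, bias = 0.5, seed = 1L,
                            shape = c(64, 64, 64),
                            pattern = fiber_pattern("uniform"),
                            ranges = list()) {
  if (n_patients < 2)
    stop_growthtrack("growthtrack_bad_param", "n_patients must be >= 2")
  if (bias < 0 || bias > 1)
    stop_growthtrack("growthtrack_bad_param", "bias must lie in [0, 1]")
  rg <- modifyList(list(r1 = c(5, 8), center_jitter = 4,
                        factor_parallel = 1.5, factor_perpendicular = 1.1,
                        interval_days = c(4L, 97L)), ranges)
  if (rg$interval_days[1] > rg$interval_days[2] || rg$r1[1] > rg$r1[2])
    stop_growthtrack("growthtrack_bad_param", "degenerate simulation range")
  shape <- as.integer(shape)
  affine <- center_affine(shape)
  template <- generate_fiber_field(shape, pattern, affine)

  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(seed + i)
    r1 <- runif(1, rg$r1[1], rg$r1[2])
    center <- runif(3, -rg$center_jitter, rg$center_jitter)
    along <- runif(1) < bias
    fp <- rg$factor_parallel
    fq <- rg$factor_perpendicular
    spec <- if (along) {
      growth_spec(center = center, r1 = r1, mode = "along_fiber",
                  factor_parallel = fp, factor_perpendicular = fq,
                  seed = seed + i)
    } else {
      growth_spec(center = center, r1 = r1,
                  mode = "random_isotropic_vectors",
                  factor = (fp * fq^2)^(1 / 3), seed = seed + i)
    }
    sim <- simulate_tumor_growth(shape, spec, fibers = template,
                                 affine = affine)
    patients[[i]] <- list(
      id = sprintf("P%03d", i), t1 = sim$t1, t2 = sim$t2, truth = sim$truth,
      interval_days = sample(seq(rg$interval_days[1], rg$interval_days[2]), 1),
      mgmt = sample(mgmt_levels, 1, prob = mgmt_probs),
      mode = spec$mode)
  }
  metadata <- data.frame(
    patient_id = vapply(patients, `[[`, "", "id"),
    interval_days = vapply(patients, `[[`, 0L, "interval_days"),
    mgmt = vapply(patients, `[[`, "", "mgmt"),
    stringsAsFactors = FALSE)
  list(template = template, patients = patients, metadata = metadata)
}

#' Generate a cohort directory on disk
#'
#' Writes the layout `cohort/<patient_id>/{t1_mask,t2_mask,t1_img,t2_img}`
#' (NIfTI), a per-patient `truth.json` (ground-truth volumes, histogram and
#' the growth spec needed to reconstruct the analytic deformation), the
#' shared `template_tensor.nii.gz` and `metadata.csv`.
#'
#' @inheritParams simulate_cohort
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_cohort <- function(dir, n_patients, bias = 0.5, seed = 1L,
                            shape = c(64, 64, 64),
                            pattern = fiber_pattern("uniform"),
                            ranges = list()) {
  co <- simulate_cohort(n_patients, bias = bias, seed = seed, shape = shape,
                        pattern = pattern, ranges = ranges)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(co$template, file.path(dir, "template_tensor.nii.gz"))
  for (p in co$patients) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    write_volume(p$t1, file.path(pd, "t1_mask.nii.gz"))
    write_volume(p$t2, file.path(pd, "t2_mask.nii.gz"))
    write_volume(synthetic_t1_image(p$t1, seed = p$truth$spec$seed),
                 file.path(pd, "t1_img.nii.gz"))
    write_volume(synthetic_t1_image(p$t2, seed = p$truth$spec$seed),
                 file.path(pd, "t2_img.nii.gz"))
    truth <- p$truth
    spec <- truth$spec
    jsonlite::write_json(list(
      v1 = truth$v1, v2 = truth$v2, axis = truth$axis,
      mode = spec$mode, center = spec$center, r1 = spec$r1,
      factor_parallel = spec$factor_parallel,
      factor_perpendicular = spec$factor_perpendicular,
      bin_fractions = if (!is.null(truth$true_angle_histogram))
        truth$true_angle_histogram$bin_fractions,
      parallel_fraction = if (!is.null(truth$true_angle_histogram))
        truth$true_angle_histogram$parallel_fraction,
      perpendicular_fraction = if (!is.null(truth$true_angle_histogram))
        truth$true_angle_histogram$perpendicular_fraction
    ), file.path(pd, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(co$metadata, file.path(dir, "metadata.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
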
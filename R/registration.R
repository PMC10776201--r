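# Registration chain: 12-parameter affine registration between scalar
# volumes, resampling through affine transforms, and mask-to-mask B-spline
# free-form deformable registration on signed distance maps, producing the
# dense growth deformation field.

#' Signed Euclidean distance map of a mask
#'
#' Distance in mm to the mask surface: negative inside, positive outside,
#' near zero on the boundary shell.  Computed with an exact Euclidean
#' distance transform that honours anisotropic voxel spacing.
#'
#' @param mask a nonempty [mask_volume].
#' @return A [volume_image] of signed distances (mm).
#' @export
signed_distance <- function(mask) {
  if (!inherits(mask, "mask_volume"))
    stop_growthtrack("growthtrack_bad_type", "input must be a mask_volume")
  inside <- mask$data > 0.5
  if (!any(inside))
    stop_growthtrack("growthtrack_empty_mask", "mask is empty")
  sp <- voxel_spacing(mask)
  shape <- vol_shape(mask)
  d_out <- sqrt(cpp_edt2(as.logical(inside), shape, sp))
  d_in <- if (all(inside)) rep(0, length(inside))
          else sqrt(cpp_edt2(!inside, shape, sp))
  volume_image(array(d_out - d_in, shape), mask$affine)
}

#' Dice overlap coefficient of two masks
#' @param a,b [mask_volume]s on the same grid.
#' @export
dice_coefficient <- function(a, b) {
  require_same_grid(a, b, "masks")
  ai <- a$data > 0.5; bi <- b$data > 0.5
  2 * sum(ai & bi) / (sum(ai) + sum(bi))
}

# ---------------------------------------------------------------------------
# Affine registration (12 dof: translation, rotation, scale, shear)
# ---------------------------------------------------------------------------

rot3 <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# p = (tx ty tz, rx ry rz [rad], sx sy sz, kxy kxz kyz), about centre c (mm)
params_to_affine <- function(p, center = c(0, 0, 0)) {
  S <- diag(p[7:9])
  K <- diag(3); K[1, 2] <- p[10]; K[1, 3] <- p[11]; K[2, 3] <- p[12]
  L <- rot3(p[4:6]) %*% K %*% S
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- p[1:3] + center - L %*% center
  M
}

identity_params <- function() c(rep(0, 3), rep(0, 3), rep(1, 3), rep(0, 3))

downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  shape <- vol_shape(vol)
  ix <- seq(1, shape[1], by = f)
  iy <- seq(1, shape[2], by = f)
  iz <- seq(1, shape[3], by = f)
  A <- vol$affine
  A[1:3, 1:3] <- A[1:3, 1:3] * f
  volume_image(vol$data[ix, iy, iz, drop = FALSE], A)
}

#' Affine registration of two scalar volumes
#'
#' Recovers the 12-degree-of-freedom world-to-world transform (translation,
#' rotation, scale, shear) mapping the moving volume onto the fixed one by
#' multi-resolution minimization of the mean squared intensity difference,
#' using quasi-Newton (BFGS) descent with finite-difference gradients.
#' Deterministic given inputs and parameters.
#'
#' @param moving,fixed [volume_image]s with overlapping fields of view;
#'   both must be nonconstant.
#' @param levels integer downsampling factors, coarse to fine.
#' @param max_iter BFGS iteration cap per level.
#' @param stride voxel stride for metric sampling at the finest level.
#' @param tol required relative metric improvement over the identity; if the
#'   optimum is not this much better, a diagnostic error carrying the metric
#'   trace is raised.
#' @return An [affine_transform] mapping moving world coordinates to fixed
#'   world coordinates, with the per-level metric trace in attribute
#'   `"trace"`.
#' @export
affine_register <- function(moving, fixed, levels = c(4, 2, 1),
                            max_iter = 100, stride = 2, tol = 1e-8) {
  for (v in list(moving, fixed))
    if (max(v$data) == min(v$data))
      stop_growthtrack("growthtrack_bad_param",
                       "cannot register a constant volume")
  shape_f <- vol_shape(fixed)
  center <- as.vector(fixed$affine %*% c((shape_f - 1) / 2, 1))[1:3]
  inv_mov <- solve(moving$affine)

  p <- identity_params()
  trace <- list()
  cost <- NULL
  for (f in levels) {
    if (any(vol_shape(fixed) < 8 * f)) next
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    inv_mv <- solve(mv$affine)
    st <- if (f == 1) as.integer(stride) else 1L
    cost <- local({
      fx <- fx; mv <- mv; inv_mv <- inv_mv; st <- st
      function(pp) {
        Tm <- params_to_affine(pp, center)
        inv_Tm <- tryCatch(solve(Tm), error = function(e) NULL)
        if (is.null(inv_Tm)) return(1e12)   # degenerate parameter point
        M <- inv_mv %*% inv_Tm %*% fx$affine
        cpp_affine_ssd(mv$data, vol_shape(mv), fx$data, vol_shape(fx),
                       M, st)
      }
    })
    opt <- optim(p, cost, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12,
                                ndeps = c(rep(1e-2, 3), rep(1e-3, 3),
                                          rep(1e-3, 3), rep(1e-3, 3))))
    trace[[length(trace) + 1]] <- list(factor = f, start = cost(p),
                                       end = opt$value)
    p <- opt$par
  }
  c_id <- cost(identity_params())
  c_fin <- cost(p)
  if (is.finite(c_id) && c_id > 0 && (c_id - c_fin) <= tol * c_id) {
    cond <- structure(
      class = c("growthtrack_registration_failure", "growthtrack_error",
                "error", "condition"),
      list(message = "affine registration failed to improve on the identity",
           call = sys.call(), trace = trace))
    stop(cond)
  }
  t <- affine_transform(params_to_affine(p, center))
  attr(t, "trace") <- trace
  attr(t, "params") <- p
  t
}

#' Write / read an affine transform as plain text
#'
#' Row-major 4x4 matrix, one row per line, whitespace separated.
#'
#' @param t an [affine_transform].
#' @param path file path.
#' @export
write_affine_transform <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  writeLines(apply(t$matrix, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_affine_transform
#' @export
read_affine_transform <- function(path) {
  if (!file.exists(path))
    stop_growthtrack("growthtrack_missing_file", "file not found: '%s'", path)
  rows <- strsplit(trimws(readLines(path, n = 4)), "\\s+")
  m <- do.call(rbind, lapply(rows, as.numeric))
  affine_transform(m)
}

#' Resample an image or mask through an affine transform
#'
#' Samples the input on the reference grid: trilinear interpolation for
#' scalar images, nearest-neighbour for masks (binarized at > 0.5).
#' Out-of-field voxels are set to 0.  When the transform is the identity
#' and the grids match, the input is returned unchanged (bit-identical).
#'
#' @param image a [volume_image] or [mask_volume].
#' @param t an [affine_transform] mapping the image's world coordinates to
#'   the reference's world coordinates.
#' @param reference the grid to sample on.
#' @return The resampled object, same class as `image`.
#' @export
apply_transform <- function(image, t, reference) {
  stopifnot(inherits(t, "affine_transform"))
  if (max(abs(t$matrix - diag(4))) < 1e-12 && same_grid(image, reference))
    return(image)
  shape <- vol_shape(reference)
  pts_w <- voxel_centers_world(shape, reference$affine)
  inv_t <- solve(t$matrix)
  mov_w <- sweep(pts_w %*% t(inv_t[1:3, 1:3]), 2, inv_t[1:3, 4], `+`)
  vox <- world_to_voxel(mov_w, image$affine)
  is_mask <- inherits(image, "mask_volume")
  vals <- cpp_sample_points(image$data, vol_shape(image), vox,
                            if (is_mask) 1L else 0L, 0.0, 0.5)
  arr <- array(vals, shape)
  if (is_mask) mask_volume(arr, reference$affine)
  else volume_image(arr, reference$affine)
}

#' Resample a tensor volume through an affine transform
#'
#' Components are interpolated trilinearly on the reference grid; by
#' default the tensors are then reoriented with the rotation component of
#' the transform (polar decomposition of its linear part), so principal
#' directions follow the anatomy.  `reorient = FALSE` gives the strict
#' resample-only behaviour.
#'
#' @param tensors a [tensor_volume].
#' @param t an [affine_transform] (tensor space to reference space).
#' @param reference grid to sample on.
#' @param reorient apply the rotation to the tensors (default TRUE).
#' @export
apply_transform_tensor <- function(tensors, t, reference, reorient = TRUE) {
  stopifnot(inherits(tensors, "tensor_volume"))
  shape <- vol_shape(reference)
  pts_w <- voxel_centers_world(shape, reference$affine)
  inv_t <- solve(t$matrix)
  mov_w <- sweep(pts_w %*% t(inv_t[1:3, 1:3]), 2, inv_t[1:3, 4], `+`)
  vox <- world_to_voxel(mov_w, tensors$affine)
  comp <- vapply(1:6, function(c)
    cpp_sample_points(tensors$data[, , , c], vol_shape(tensors), vox,
                      0L, 0.0, 0.5),
    numeric(nrow(vox)))
  if (reorient) {
    L <- t$matrix[1:3, 1:3]
    sv <- svd(L)
    R <- sv$u %*% t(sv$v)          # rotation factor of the polar decomposition
    if (det(R) < 0) R <- -R
    xx <- comp[, 1]; xy <- comp[, 2]; xz <- comp[, 3]
    yy <- comp[, 4]; yz <- comp[, 5]; zz <- comp[, 6]
    out <- matrix(0, nrow(comp), 6)
    for (i in 1:3) for (j in i:3) {
      # (R D R^T)_ij expanded over the six unique components
      v <- R[i, 1] * (R[j, 1] * xx + R[j, 2] * xy + R[j, 3] * xz) +
           R[i, 2] * (R[j, 1] * xy + R[j, 2] * yy + R[j, 3] * yz) +
           R[i, 3] * (R[j, 1] * xz + R[j, 2] * yz + R[j, 3] * zz)
      k <- c(`11` = 1, `12` = 2, `13` = 3, `22` = 4, `23` = 5, `33` = 6)
      out[, k[[paste0(i, j)]]] <- v
    }
    comp <- out
  }
  tensor_volume(array(comp, c(shape, 6L)), reference$affine,
                diagonal_only = tensors$diagonal_only)
}

# ---------------------------------------------------------------------------
# B-spline free-form deformable registration
# ---------------------------------------------------------------------------

#' Parameters for deformable registration
#'
#' @param levels number of multi-resolution levels (>= 1).  The default is
#'   a single level: the clamped-distance metric already has a capture
#'   range far beyond typical interscan tumor displacements, and coarse
#'   control lattices (16-32 mm) cannot represent a localized expansion, so
#'   extra pyramid levels seed the fine solve with a smooth wrong fit whose
#'   tangential part the metric cannot correct.  Use more levels only for
#'   displacements beyond the capture range.
#' @param control_spacing_mm B-spline control-point spacing at the finest
#'   level (mm); it doubles per coarser level (exact dyadic knot
#'   insertion between levels).
#' @param lambda bending-energy regularization weight.
#' @param max_iter optimizer iteration cap per level.
#' @param tol relative metric-change convergence tolerance.
#' @param dmax_mm signed distance maps are clamped at this magnitude, which
#'   localizes the metric to a band around the surfaces.
#' @param metric `"ssd_distance"` (default: SSD on clamped signed distance
#'   maps of the masks) or `"ssd_image_excluded"` (SSD on scalar images with
#'   the tumor union excluded from the metric).
#' @export
registration_params <- function(levels = 1, control_spacing_mm = 8,
                                lambda = 0.01, max_iter = 50, tol = 1e-5,
                                dmax_mm = 10,
                                metric = c("ssd_distance",
                                           "ssd_image_excluded")) {
  if (levels < 1 || control_spacing_mm <= 0)
    stop_growthtrack("growthtrack_bad_param",
                     "levels must be >= 1 and spacing > 0")
  structure(list(levels = as.integer(levels),
                 control_spacing_mm = control_spacing_mm, lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol,
                 dmax_mm = dmax_mm, metric = match.arg(metric)),
            class = "registration_params")
}

subsample_array <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr)
  arr[seq(1, d[1], by = f), seq(1, d[2], by = f), seq(1, d[3], by = f),
      drop = FALSE]
}

clamped_distance <- function(mask_arr, spacing, dmax) {
  d <- dim(mask_arr)
  inside <- mask_arr > 0.5
  d_out <- sqrt(cpp_edt2(as.logical(inside), d, spacing))
  d_in <- sqrt(cpp_edt2(!inside, d, spacing))
  pmin(pmax(array(d_out - d_in, d), -dmax), dmax)
}

# Exact dyadic refinement of a cubic B-spline control lattice (knot
# insertion): even fine nodes (c[j-1] + 6 c[j] + c[j+1]) / 8, odd nodes
# (c[j] + c[j+1]) / 2, per axis, with zero padding outside the lattice.
subdivide_cp <- function(prev, cpdim_fine) {
  sub_axis <- function(A, nfine) {
    d <- dim(A)
    cc <- d[1]
    flat <- matrix(A, cc)
    zr <- function(j) {
      ok <- j >= 0 & j <= cc - 1
      out <- matrix(0, length(j), ncol(flat))
      out[ok, ] <- flat[j[ok] + 1, , drop = FALSE]
      out
    }
    k <- 0:(nfine - 1)
    je <- k %/% 2
    out <- matrix(0, nfine, ncol(flat))
    even <- k %% 2 == 0
    out[even, ] <- (zr(je[even] - 1) + 6 * zr(je[even]) + zr(je[even] + 1)) / 8
    out[!even, ] <- (zr(je[!even]) + zr(je[!even] + 1)) / 2
    array(out, c(nfine, d[-1]))
  }
  A <- prev
  for (ax in 1:3) {
    A <- aperm(A, c(ax, setdiff(1:4, ax)))
    A <- sub_axis(A, cpdim_fine[ax])
    A <- aperm(A, order(c(ax, setdiff(1:4, ax))))
  }
  A
}

# one L-BFGS-B solve of the FFD control grid; fn/gr share one evaluation
ffd_optimize <- function(cp0, cpdim, fixv, movv, dim, delta, active, lambda,
                         max_iter, tol) {
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      cache$res <- cpp_ffd_cost_grad(par, cpdim, fixv, movv, dim, delta,
                                     active, lambda, TRUE)
      cache$par <- par
    }
    cache$res
  }
  fn <- function(par) evaluate(par)$cost
  gr <- function(par) evaluate(par)$grad
  opt <- optim(cp0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter,
                              factr = tol / .Machine$double.eps))
  opt
}

#' Deformable registration of two tumor masks
#'
#' Estimates a cubic B-spline free-form deformation aligning the baseline
#' (moving) mask with the follow-up (fixed) mask, by multi-resolution
#' minimization of the SSD between clamped signed distance maps of the
#' masks (distance maps give smooth gradients where binary masks have
#' none), with a bending-energy penalty on the control lattice.  The
#' optimization runs inside a region of interest around the mask union;
#' the displacement is identically zero outside that dilated union, which
#' keeps the deformation field local to the lesion.
#'
#' The returned field follows the growth convention: it is the displacement
#' (mm, world frame) that carries the baseline material point observed at
#' each voxel of the fixed grid from its baseline position to that voxel —
#' growth vectors point outward for an expanding lesion.
#'
#' @param moving baseline (timepoint-1) [mask_volume].
#' @param fixed follow-up (timepoint-2) [mask_volume] on the same grid.
#' @param params a [registration_params].
#' @param moving_image,fixed_image scalar [volume_image]s, used only by the
#'   `"ssd_image_excluded"` metric (registration of the surrounding image
#'   with the tumor union excluded from the metric).
#' @return A [deformation_volume] on the fixed grid.  Attributes:
#'   `"warped_mask"` (the moving mask carried through the estimated
#'   transform, for overlap checks), `"dice"`, `"trace"` (per-level metric
#'   start/end) and `"params"`.
#' @export
nonlinear_register_masks <- function(moving, fixed,
                                     params = registration_params(),
                                     moving_image = NULL,
                                     fixed_image = NULL) {
  if (!any(moving$data > 0.5) || !any(fixed$data > 0.5))
    stop_growthtrack("growthtrack_empty_mask", "masks must be nonempty")
  require_same_grid(moving, fixed, "masks")
  sp <- voxel_spacing(fixed)
  shape <- vol_shape(fixed)

  union <- moving$data > 0.5 | fixed$data > 0.5
  uidx <- which(union, arr.ind = TRUE)
  margin_mm <- params$control_spacing_mm + 4
  mv <- ceiling(margin_mm / sp)
  lo <- pmax(apply(uidx, 2, min) - mv, 1)
  hi <- pmin(apply(uidx, 2, max) + mv, shape)
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cshape <- hi - lo + 1

  mmask <- crop(moving$data)
  fmask <- crop(fixed$data)
  use_images <- params$metric == "ssd_image_excluded"
  if (use_images) {
    if (is.null(moving_image) || is.null(fixed_image))
      stop_growthtrack("growthtrack_bad_param",
                       "ssd_image_excluded metric needs both images")
    mimg <- crop(moving_image$data)
    fimg <- crop(fixed_image$data)
  }

  # full-resolution distance maps once; levels subsample the smooth field
  # (recomputing distances from subsampled masks would re-voxelize the
  # surface and inject spurious tangential gradients at coarse levels)
  fdist <- clamped_distance(fmask, sp, params$dmax_mm)
  mdist <- clamped_distance(mmask, sp, params$dmax_mm)

  factors <- 2^((params$levels - 1):0)
  factors <- factors[cshape[1] / factors >= 8 | factors == 1]
  cp <- NULL
  trace <- list()
  for (f in factors) {
    msub <- subsample_array(mmask, f)
    fsub <- subsample_array(fmask, f)
    dim_l <- dim(msub)
    sp_l <- sp * f
    # physical control spacing control_spacing_mm * f at this level, i.e. a
    # constant delta in level voxels; coarse levels have few, stiff dof and
    # are refined exactly by knot insertion
    delta <- rep(params$control_spacing_mm, 3) / sp
    cpdim <- floor((dim_l - 1) / delta) + 4
    if (use_images) {
      fixv <- subsample_array(fimg, f)
      movv <- subsample_array(mimg, f)
      active <- which(!(msub > 0.5 | fsub > 0.5)) - 1L
    } else {
      fixv <- subsample_array(fdist, f)
      movv <- subsample_array(mdist, f)
      band <- abs(fixv) < params$dmax_mm | abs(movv) < params$dmax_mm
      active <- which(band) - 1L
    }
    cp0 <- if (is.null(cp)) {
      numeric(prod(cpdim) * 3)
    } else {
      # refine the coarser lattice exactly (dyadic knot insertion), then
      # rescale displacements to the finer voxel units
      ratio <- f_prev / f
      as.vector(subdivide_cp(array(cp, c(cpdim_prev, 3L)), cpdim) * ratio)
    }
    opt <- ffd_optimize(cp0, cpdim, as.vector(fixv), as.vector(movv), dim_l,
                        delta, as.integer(active), params$lambda,
                        params$max_iter, params$tol)
    start_cost <- cpp_ffd_cost_grad(cp0, cpdim, as.vector(fixv),
                                    as.vector(movv), dim_l, delta,
                                    as.integer(active), params$lambda,
                                    FALSE)$cost
    if (opt$value > start_cost + 1e-12)
      stop_growthtrack("growthtrack_registration_divergence",
                       "deformable registration diverged at level %d", f)
    trace[[length(trace) + 1]] <- list(factor = f, start = start_cost,
                                       end = opt$value)
    cp <- opt$par
    cpdim_prev <- cpdim
    delta_prev <- delta
    f_prev <- f
  }

  # dense displacement (voxel units of the crop grid) at the finest level
  v_vox <- array(cpp_ffd_field(cp, cpdim_prev, cshape, delta_prev),
                 c(cshape, 3L))

  # warp the moving mask onto the fixed grid for overlap diagnostics:
  # sample its signed distance map and threshold at the zero level set,
  # which keeps sub-voxel surface accuracy
  base <- as.matrix(expand.grid(x = seq_len(cshape[1]) - 1,
                                y = seq_len(cshape[2]) - 1,
                                z = seq_len(cshape[3]) - 1))
  warped_d <- cpp_sample_points(mdist, cshape,
                                base + matrix(v_vox, ncol = 3), 0L,
                                params$dmax_mm, 0.5)
  warped <- moving$data
  warped[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    array(as.double(warped_d <= 0), cshape)

  # growth field: -v, in world mm, embedded in the full grid
  u_full <- array(0, c(shape, 3L))
  lin <- fixed$affine[1:3, 1:3]
  u_w <- -matrix(v_vox, ncol = 3) %*% t(lin)
  # zero outside the union dilated by the ROI margin
  dil <- sqrt(cpp_edt2(as.logical(crop(array(union, shape))), cshape,
                       sp)) <= margin_mm
  u_w[!as.vector(dil), ] <- 0
  for (c in 1:3)
    u_full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c] <- u_w[, c]

  def <- deformation_volume(u_full, fixed$affine)
  wm <- mask_volume(warped, fixed$affine)
  attr(def, "warped_mask") <- wm
  attr(def, "dice") <- dice_coefficient(wm, fixed)
  attr(def, "trace") <- trace
  attr(def, "params") <- params
  def
}
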
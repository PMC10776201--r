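# Affine and deformable registration: recovery of known transforms and
# analytic deformation fields

test_that("signed distance matches analytic values on a sphere", {
  m <- sphere_mask(c(32, 32, 32), r = 8)
  sd <- signed_distance(m)
  ctr <- round(growthtrack:::world_to_voxel(matrix(0, 1, 3), m$affine)) + 1
  expect_lt(abs(sd$data[ctr[1], ctr[2], ctr[3]] + 8), 1)
  pts <- growthtrack:::voxel_centers_world(c(32, 32, 32), m$affine)
  r <- sqrt(rowSums(pts^2))
  boundary <- abs(r - 8) <= 0.5
  expect_lt(max(abs(as.vector(sd$data)[boundary])), sqrt(3) + 0.5)
  outside <- r > 9 & r < 14
  expect_lt(max(abs(as.vector(sd$data)[outside] - (r[outside] - 8))), 1)
  empty <- mask_volume(array(0, c(4, 4, 4)))
  expect_error(signed_distance(empty), class = "growthtrack_empty_mask")
})

test_that("self-registration returns the identity", {
  ph <- make_structured_phantom(c(40, 40, 40), seed = 1)
  t <- affine_register(ph, ph)
  p <- attr(t, "params")
  expect_lt(max(abs(p[1:3])), 1e-3)        # translation, mm
  expect_lt(max(abs(p[4:6])), 1e-4)        # rotation, rad
  expect_lt(max(abs(p[7:9] - 1)), 1e-4)    # scale
})

test_that("known translations and scalings are recovered", {
  ph <- make_structured_phantom(c(48, 48, 48), seed = 2)
  tr <- affine_transform(rbind(c(1, 0, 0, 3), c(0, 1, 0, -2),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
  rec <- affine_register(ph, apply_transform(ph, tr, ph))
  expect_lt(max(abs(rec$matrix[1:3, 4] - c(3, -2, 0))), 0.2)

  sc <- affine_transform(diag(c(1.1, 1.1, 1.1, 1)))
  rec2 <- affine_register(ph, apply_transform(ph, sc, ph))
  expect_lt(max(abs(attr(rec2, "params")[7:9] - 1.1)), 0.011)
})

test_that("random small rigid+scale perturbations are recovered", {
  ph <- make_structured_phantom(c(48, 48, 48), seed = 3)
  set.seed(4)
  for (i in 1:3) {
    p_true <- c(runif(3, -5, 5), runif(3, -1, 1) * 5 * pi / 180,
                runif(3, 0.95, 1.05), rep(0, 3))
    t_true <- affine_transform(growthtrack:::params_to_affine(
      p_true, center = c(0, 0, 0)))
    moved <- apply_transform(ph, t_true, ph)
    rec <- affine_register(ph, moved)
    p_rec <- attr(rec, "params")
    expect_lt(max(abs(p_rec[1:3] - p_true[1:3])), 0.3)
    expect_lt(max(abs(p_rec[4:6] - p_true[4:6])), 0.5 * pi / 180)
    expect_lt(max(abs(p_rec[7:9] - p_true[7:9])), 0.01)
  }
})

test_that("apply_transform behaves on identity, translation and inversion", {
  m <- sphere_mask(c(32, 32, 32), r = 6)
  idt <- affine_transform(diag(4))
  expect_identical(apply_transform(m, idt, m), m)

  tr <- affine_transform(rbind(c(1, 0, 0, 5), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
  shifted <- apply_transform(m, tr, m)
  centroid <- function(msk) {
    pts <- growthtrack:::voxel_centers_world(dim(msk$data), msk$affine)
    colMeans(pts[msk$data > 0.5, ])
  }
  expect_lt(abs(centroid(shifted)[1] - centroid(m)[1] - 5), 0.5)

  rot <- growthtrack:::params_to_affine(
    c(1, 2, 0, 0.1, 0, 0.05, 1, 1, 1, 0, 0, 0))
  t1 <- affine_transform(rot)
  t2 <- affine_transform(solve(rot))
  back <- apply_transform(apply_transform(m, t1, m), t2, m)
  expect_gte(dice_coefficient(back, m), 0.99)
})

test_that("identical masks register to a near-zero field", {
  m <- sphere_mask(c(48, 48, 48), r = 7)
  def <- nonlinear_register_masks(m, m)
  mag <- sqrt(rowSums(matrix(def$data, ncol = 3)^2))
  expect_lt(mean(mag[as.vector(m$data > 0.5)]), 0.1)
})

test_that("concentric sphere growth registers radially", {
  shape <- c(64, 64, 64)
  sim <- simulate_tumor_growth(shape, growth_spec(r1 = 5, mode = "isotropic",
                                                  factor = 1.4))
  def <- nonlinear_register_masks(sim$t1, sim$t2)
  expect_gte(attr(def, "dice"), 0.95)
  u <- matrix(def$data, ncol = 3)
  pts <- growthtrack:::voxel_centers_world(shape, sim$t1$affine)
  rad <- pts / pmax(sqrt(rowSums(pts^2)), 1e-9)
  grow <- as.vector(sim$t2$data > 0.5 & sim$t1$data <= 0.5)
  on_bd <- grow & sqrt(rowSums(u^2)) > 0.1
  ang <- acos(pmin(1, abs(rowSums(u * rad))[on_bd] /
                      sqrt(rowSums(u^2))[on_bd])) * 180 / pi
  expect_gte(mean(ang <= 15), 0.9)
})

test_that("sphere-to-ellipsoid registration recovers the analytic field", {
  shape <- c(64, 64, 64)
  sim <- simulate_tumor_growth(
    shape, growth_spec(r1 = 6, mode = "fixed_direction", axis = c(1, 0, 0),
                       factor_parallel = 1.5, factor_perpendicular = 1.0))
  def <- nonlinear_register_masks(sim$t1, sim$t2)
  expect_gte(attr(def, "dice"), 0.95)
  ut <- matrix(sim$truth$true_deformation$data, ncol = 3)
  ur <- matrix(def$data, ncol = 3)
  grow <- as.vector(sim$t2$data > 0.5 & sim$t1$data <= 0.5)
  mee <- mean(sqrt(rowSums((ut - ur)^2))[grow])
  expect_lte(mee, 1.0)
  # direction agreement over the growth region
  ok <- grow & sqrt(rowSums(ur^2)) > 0.1
  ang <- acos(pmin(1, abs(rowSums(ut * ur)) /
                   (sqrt(rowSums(ut^2)) * sqrt(rowSums(ur^2)))))[ok] * 180 / pi
  expect_gte(mean(ang <= 20), 0.8)
})

test_that("the deformation vanishes outside the dilated mask union", {
  shape <- c(48, 48, 48)
  sim <- simulate_tumor_growth(shape, growth_spec(r1 = 5, mode = "isotropic",
                                                  factor = 1.3))
  def <- nonlinear_register_masks(sim$t1, sim$t2)
  sp <- growthtrack:::voxel_spacing(sim$t1)
  union <- sim$t1$data > 0.5 | sim$t2$data > 0.5
  dist_u <- sqrt(growthtrack:::cpp_edt2(as.logical(union), shape, sp))
  far <- as.vector(dist_u) > 12  # beyond the ROI margin
  mag <- sqrt(rowSums(matrix(def$data, ncol = 3)^2))
  expect_identical(max(mag[far]), 0)
})

test_that("affine transforms round trip through plain text", {
  t <- affine_transform(growthtrack:::params_to_affine(
    c(1.5, -2, 0.25, 0.1, -0.05, 0.2, 1.02, 0.98, 1, 0.01, 0, -0.02)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_affine_transform(t, f)
  back <- read_affine_transform(f)
  expect_equal(back$matrix, t$matrix, tolerance = 1e-15)
})

test_that("tensor resampling reorients principal directions by default", {
  shape <- c(16, 16, 16)
  tv <- generate_fiber_field(shape, fiber_pattern("uniform",
                                                  direction = c(1, 0, 0)))
  # rotate 90 degrees about z: x-fibers should become y-fibers
  rot <- growthtrack:::params_to_affine(
    c(0, 0, 0, 0, 0, pi / 2, 1, 1, 1, 0, 0, 0))
  ref <- volume_image(array(0, shape), tv$affine)
  out <- apply_transform_tensor(tv, affine_transform(rot), ref)
  d <- principal_direction_map(out)
  mid <- d$direction[8, 8, 8, ]
  expect_lt(angle_between(mid, c(0, 1, 0)), 1e-6)
  # without reorientation the tensors keep their original frame
  out2 <- apply_transform_tensor(tv, affine_transform(rot), ref,
                                 reorient = FALSE)
  d2 <- principal_direction_map(out2)
  expect_lt(angle_between(d2$direction[8, 8, 8, ], c(1, 0, 0)), 1e-6)
})

test_that("registration rejects empty masks and mismatched grids", {
  m <- sphere_mask(c(24, 24, 24), r = 5)
  empty <- mask_volume(array(0, c(24, 24, 24)), m$affine)
  expect_error(nonlinear_register_masks(empty, m),
               class = "growthtrack_empty_mask")
  other <- sphere_mask(c(20, 20, 20), r = 5)
  expect_error(nonlinear_register_masks(m, other),
               class = "growthtrack_grid_mismatch")
})
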
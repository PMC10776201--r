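# Angle computation, voxel selection, histogram binning

test_that("angles reproduce the analytic cases with sign/scale invariance", {
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90, tolerance = 1e-12)
  expect_equal(angle_between(c(1, 1, 0), c(1, 0, 0)), 45, tolerance = 1e-12)
  expect_equal(angle_between(c(-1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(angle_between(c(2, 2, 0), c(-5, 0, 0)), 45, tolerance = 1e-12)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)),
               class = "growthtrack_zero_vector")
})

test_that("voxel selection gates on union, magnitude and validity", {
  shape <- c(24, 24, 24)
  aff <- growthtrack:::center_affine(shape)
  t1 <- sphere_mask(shape, r = 4, affine = aff)
  t2 <- sphere_mask(shape, r = 6, affine = aff)
  dirs <- uniform_dirs_field(shape, affine = aff)
  union_n <- sum(t1$data > 0.5 | t2$data > 0.5)

  zero <- deformation_volume(array(0, c(shape, 3)), aff)
  sel0 <- select_growth_voxels(zero, t1, t2, dirs)
  expect_identical(length(sel0$idx), 0L)
  expect_identical(unname(sel0$exclusions["below_magnitude"]), union_n)

  u <- array(0, c(shape, 3))
  u[, , , 1] <- 0.2  # 2 * eps everywhere
  sel1 <- select_growth_voxels(deformation_volume(u, aff), t1, t2, dirs)
  expect_identical(length(sel1$idx), union_n)

  # half the union below threshold
  half <- array(0, c(shape, 3))
  idx_union <- which(t1$data > 0.5 | t2$data > 0.5)
  on <- idx_union[seq_len(floor(union_n / 2))]
  comp1 <- array(0, shape); comp1[on] <- 1
  half[, , , 1] <- comp1
  sel2 <- select_growth_voxels(deformation_volume(half, aff), t1, t2, dirs)
  expect_identical(length(sel2$idx), length(on))
})

test_that("histogram binning matches hand-worked fractions and edges", {
  dirs <- matrix(c(1, 0, 0), 3, 3, byrow = TRUE)
  ang <- c(5, 15, 85) * pi / 180
  vecs <- cbind(cos(ang), sin(ang), 0)
  h <- bin_histogram(growth_voxel_set(vecs, dirs))
  expect_equal(h$bin_fractions,
               c(1, 1, 0, 0, 0, 0, 0, 0, 1) / 3, tolerance = 1e-12)
  expect_equal(h$parallel_fraction, 2 / 3, tolerance = 1e-12)
  expect_equal(h$perpendicular_fraction, 1 / 3, tolerance = 1e-12)

  # all angles zero
  h0 <- bin_histogram(growth_voxel_set(dirs, dirs))
  expect_identical(h0$bin_fractions[1], 1)

  # boundary conventions: bins are half-open below, and the last bin is
  # closed at 90 (orthogonal vectors have an exact zero dot product, so 90
  # is reached exactly); just above an edge belongs to the upper bin
  h90 <- bin_histogram(growth_voxel_set(rbind(c(0, 1, 0)), rbind(c(1, 0, 0))))
  expect_identical(h90$bin_fractions[9], 1)
  expect_identical(h90$perpendicular_fraction, 1)
  eps <- 1e-6
  near <- c(20 + eps, 20 - eps, 70 + eps, 70 - eps) * pi / 180
  hn <- bin_histogram(growth_voxel_set(cbind(cos(near), sin(near), 0),
                                       matrix(c(1, 0, 0), 4, 3, byrow = TRUE)))
  expect_equal(hn$bin_fractions[2], 0.25, tolerance = 1e-12)  # 20 - eps
  expect_equal(hn$bin_fractions[3], 0.25, tolerance = 1e-12)  # 20 + eps
  expect_equal(hn$bin_fractions[7], 0.25, tolerance = 1e-12)  # 70 - eps
  expect_equal(hn$bin_fractions[8], 0.25, tolerance = 1e-12)  # 70 + eps
  expect_equal(hn$parallel_fraction, 0.25, tolerance = 1e-12)
  expect_equal(hn$perpendicular_fraction, 0.25, tolerance = 1e-12)
})

test_that("magnitude weighting weighs votes by displacement length", {
  dirs <- matrix(c(1, 0, 0), 2, 3, byrow = TRUE)
  vecs <- rbind(c(3, 0, 0), c(0, 1, 0))   # 0 deg (weight 3), 90 deg (weight 1)
  h <- bin_histogram(growth_voxel_set(vecs, dirs), weighting = "magnitude")
  expect_equal(h$bin_fractions[1], 0.75, tolerance = 1e-12)
  expect_equal(h$bin_fractions[9], 0.25, tolerance = 1e-12)
})

test_that("empty voxel sets raise the non-evaluable signal", {
  expect_error(
    bin_histogram(growth_voxel_set(matrix(0, 0, 3), matrix(0, 0, 3))),
    class = "growthtrack_empty_voxelset")
})

test_that("uniform random growth reproduces the solid-angle null", {
  set.seed(123)
  n <- 1e5
  vecs <- runif_sphere(n)
  dirs <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  h <- bin_histogram(growth_voxel_set(vecs, dirs))
  expected <- null_bin_prob(seq(0, 80, 10), seq(10, 90, 10))
  expect_lt(max(abs(h$bin_fractions - expected)), 0.01)
  # parallel ~ 0.0603, perpendicular ~ 0.3420
  expect_lt(abs(h$parallel_fraction - (1 - cos(20 * pi / 180))), 0.01)
  expect_lt(abs(h$perpendicular_fraction - cos(70 * pi / 180)), 0.01)
  # within 3 standard errors per bin
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(h$bin_fractions - expected) <= 3 * se + 1e-3))
})

test_that("the histogram is invariant under joint rotation", {
  set.seed(9)
  vecs <- runif_sphere(2000) * runif(2000, 0.5, 3)
  dirs <- runif_sphere(2000)
  h1 <- bin_histogram(growth_voxel_set(vecs, dirs))
  R <- random_rotation()
  h2 <- bin_histogram(growth_voxel_set(vecs %*% t(R), dirs %*% t(R)))
  expect_lt(max(abs(h1$bin_fractions - h2$bin_fractions)), 1e-9)
})

test_that("quantify_patient composes selection, binning and volumetry", {
  shape <- c(48, 48, 48)
  tv <- generate_fiber_field(shape, fiber_pattern("uniform"))
  dirs <- principal_direction_map(tv)
  sim <- simulate_tumor_growth(
    shape, growth_spec(r1 = 5, mode = "along_fiber",
                       factor_parallel = 1.5, factor_perpendicular = 1.1),
    fibers = tv)
  pr <- quantify_patient(sim$t1, sim$t2, sim$truth$true_deformation, dirs,
                         patient_id = "T", interval_days = 19,
                         mgmt = "methylated")
  expect_gte(pr$histogram$parallel_fraction,
             pr$histogram$perpendicular_fraction)
  expect_equal(pr$v1, sim$truth$v1)
  expect_equal(pr$v2, sim$truth$v2)
  expect_equal(pr$growth_rate, 100 * log(pr$v2 / pr$v1) / 19)
  # determinism
  pr2 <- quantify_patient(sim$t1, sim$t2, sim$truth$true_deformation, dirs,
                          patient_id = "T", interval_days = 19,
                          mgmt = "methylated")
  expect_identical(pr, pr2)

  # perpendicular growth quantified from the true field
  sim_p <- simulate_tumor_growth(
    shape, growth_spec(r1 = 5, mode = "fixed_direction", axis = c(0, 1, 0),
                       factor_parallel = 1.5, factor_perpendicular = 1.0))
  pr_p <- quantify_patient(sim_p$t1, sim_p$t2,
                           sim_p$truth$true_deformation, dirs)
  expect_gte(pr_p$histogram$perpendicular_fraction, 0.9)
})
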
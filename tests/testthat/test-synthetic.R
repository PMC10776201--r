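# Phantom generator: exact anisotropy, analytic masks, ground truth,
# cohort determinism

test_that("generated tensors have the requested principal direction and FA", {
  for (fa in c(0.2, 0.6, 0.9)) {
    tv <- generate_fiber_field(c(6, 6, 6),
                               fiber_pattern("uniform", direction = c(0, 1, 0),
                                             fa_target = fa))
    df <- principal_direction_map(tv)
    expect_true(all(df$valid))
    expect_lt(max(abs(df$fa - fa)), 1e-9)
    # direction is +-(0,1,0) everywhere
    expect_lt(max(abs(abs(df$direction[, , , 2]) - 1)), 1e-9)
  }
  expect_error(fiber_pattern(fa_target = 1), class = "growthtrack_bad_param")
})

test_that("generated tensors are symmetric positive definite everywhere", {
  for (kind in c("uniform", "radial", "curved")) {
    tv <- generate_fiber_field(c(7, 7, 7), fiber_pattern(kind, fa_target = 0.7))
    tm <- matrix(tv$data, ncol = 6)
    eig <- growthtrack:::cpp_eig3_principal(tm)
    expect_gt(min(eig$values[, 3]), 0)
  }
})

test_that("radial pattern points away from the centre", {
  tv <- generate_fiber_field(c(9, 9, 9), fiber_pattern("radial"))
  df <- principal_direction_map(tv)
  # voxel displaced (d, 0, 0) from the centre: direction +-(1,0,0)
  expect_lt(angle_between(df$direction[9, 5, 5, ], c(1, 0, 0)), 1e-6)
  expect_lt(angle_between(df$direction[1, 5, 5, ], c(1, 0, 0)), 1e-6)
  expect_lt(angle_between(df$direction[5, 9, 5, ], c(0, 1, 0)), 1e-6)
})

test_that("isotropic expansion reproduces the cubed volume ratio", {
  sim <- simulate_tumor_growth(c(40, 40, 40),
                               growth_spec(r1 = 5, mode = "isotropic",
                                           factor = 1.4))
  ratio <- sim$truth$v2 / sim$truth$v1
  expect_lt(abs(ratio - 1.4^3) / 1.4^3, 0.05)
  expect_gte(sim$truth$v2, sim$truth$v1)
})

test_that("axis-aligned anisotropic growth puts its truth mass in one bin", {
  shape <- c(48, 48, 48)
  tv <- generate_fiber_field(shape, fiber_pattern("uniform"))
  sim <- simulate_tumor_growth(
    shape, growth_spec(r1 = 6, mode = "fixed_direction", axis = c(1, 0, 0),
                       factor_parallel = 1.5, factor_perpendicular = 1.0),
    fibers = tv)
  h <- sim$truth$true_angle_histogram
  expect_gte(h$bin_fractions[1], 0.95)
  expect_equal(sum(h$bin_fractions), 1, tolerance = 1e-9)
})

test_that("fixed-direction truth lands in the bin containing theta", {
  shape <- c(48, 48, 48)
  tv <- generate_fiber_field(shape, fiber_pattern("uniform"))
  for (th in c(15, 55)) {
    ax <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
    sim <- simulate_tumor_growth(
      shape, growth_spec(r1 = 6, mode = "fixed_direction", axis = ax,
                         factor_parallel = 1.5, factor_perpendicular = 1.0),
      fibers = tv)
    expect_gte(sim$truth$true_angle_histogram$bin_fractions[th %/% 10 + 1],
               0.95)
  }
})

test_that("simulation is deterministic and respects bounds", {
  spec <- growth_spec(r1 = 5, mode = "isotropic", factor = 1.3, seed = 11L)
  a <- simulate_tumor_growth(c(32, 32, 32), spec)
  b <- simulate_tumor_growth(c(32, 32, 32), spec)
  expect_identical(a, b)
  expect_error(
    simulate_tumor_growth(c(16, 16, 16),
                          growth_spec(r1 = 7, mode = "isotropic",
                                      factor = 1.4)),
    class = "growthtrack_out_of_bounds")
  expect_error(
    simulate_tumor_growth(c(32, 32, 32),
                          growth_spec(mode = "along_fiber")),
    class = "growthtrack_bad_param")
})

test_that("fully biased cohorts have parallel-dominant ground truth", {
  co <- simulate_cohort(4, bias = 1.0, seed = 3, shape = c(48, 48, 48),
                        ranges = list(r1 = c(4, 6)))
  for (p in co$patients) {
    h <- p$truth$true_angle_histogram
    expect_gt(h$parallel_fraction, h$perpendicular_fraction)
    expect_identical(p$mode, "along_fiber")
  }
  expect_true(all(co$metadata$interval_days >= 4 &
                  co$metadata$interval_days <= 97))
  expect_true(all(co$metadata$mgmt %in%
                  c("methylated", "unmethylated", "unknown")))
})

test_that("null-cohort mean ground truth approximates the solid-angle null", {
  co <- simulate_cohort(10, bias = 0.0, seed = 5, shape = c(48, 48, 48),
                        ranges = list(r1 = c(5, 7)))
  bins <- t(vapply(co$patients,
                   function(p) p$truth$true_angle_histogram$bin_fractions,
                   numeric(9)))
  expected <- null_bin_prob(seq(0, 80, 10), seq(10, 90, 10))
  # voxelized radial directions over a ball vs the continuum null
  expect_lt(max(abs(colMeans(bins) - expected)), 0.02)
})

test_that("cohort directories are reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(d1, 2, bias = 0.5, seed = 9, shape = c(24, 24, 24),
                  ranges = list(r1 = c(3, 4), center_jitter = 1))
  generate_cohort(d2, 2, bias = 0.5, seed = 9, shape = c(24, 24, 24),
                  ranges = list(r1 = c(3, 4), center_jitter = 1))
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(sort(f1))),
                   unname(tools::md5sum(sort(f2))))
})
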
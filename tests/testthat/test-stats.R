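# Cohort statistics against closed forms and reference implementations

test_that("paired t-test matches hand computation and the reference", {
  r <- paired_t_test(c(3, 5, 7), c(1, 1, 1))  # differences 2, 4, 6
  expect_equal(r$t, 4 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  expect_equal(r$cohen_d, 2.0, tolerance = 1e-12)
  ref <- t.test(c(3, 5, 7), c(1, 1, 1), paired = TRUE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  expect_error(paired_t_test(1:3, 1:4), class = "growthtrack_bad_shape")
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)),
               class = "growthtrack_degenerate")
})

test_that("paired t and ANOVA agree with stats:: on random fixtures", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)

    g <- lapply(seq_len(sample(2:3, 1)), function(j) rnorm(sample(3:20, 1)))
    av <- one_way_anova(g)
    dat <- data.frame(y = unlist(g),
                      grp = factor(rep(seq_along(g), lengths(g))))
    ref_f <- anova(lm(y ~ grp, dat))
    expect_equal(av$F, ref_f$`F value`[1], tolerance = 1e-10)
    expect_equal(av$p, ref_f$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(11, 0.5)
    av <- one_way_anova(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
  av <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(av$F, 1.5, tolerance = 1e-12)
  expect_identical(c(av$df_between, av$df_within), c(1L, 4L))
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))),
               class = "growthtrack_degenerate")
  expect_error(one_way_anova(list(1, 1:3)), class = "growthtrack_bad_param")
})

test_that("KS D equals the brute-force supremum and nortest's p", {
  set.seed(10)
  x <- rnorm(10)
  r <- ks_normality(x)
  # brute-force maximum over sample points of |F_hat - Phi_hat|
  z <- sort((x - mean(x)) / sd(x))
  n <- length(x)
  d_brute <- max(vapply(seq_len(n), function(i)
    max(abs(i / n - pnorm(z[i])), abs((i - 1) / n - pnorm(z[i]))), 0))
  expect_equal(r$D, d_brute, tolerance = 1e-12)
  expect_equal(r$D, unname(ks.test(x, "pnorm", mean(x), sd(x))$statistic),
               tolerance = 1e-12)
  expect_equal(r$p, nortest::lillie.test(x)$p.value, tolerance = 1e-12)
  expect_identical(ks_normality(rep(c(0.1, 0.5), 10), cap_p = TRUE)$p <= 0.2,
                   TRUE)
  expect_error(ks_normality(c(1, 2, 3)), class = "growthtrack_bad_param")
})

test_that("KS normality handles the minimum sample size", {
  r <- ks_normality(c(0.2, 1.4, -0.7, 2.1))   # n = 4: Monte-Carlo p
  expect_gte(r$p, 0)
  expect_lte(r$p, 1)
  expect_identical(r$n, 4L)
  r2 <- ks_normality(c(0.2, 1.4, -0.7, 2.1))  # seeded table: reproducible
  expect_identical(r, r2)
})

test_that("KS normality is calibrated and has power", {
  set.seed(11)
  p_normal <- replicate(60, ks_normality(rnorm(500))$p)
  expect_gte(mean(p_normal > 0.05), 0.9)
  p_exp <- replicate(30, ks_normality(rexp(500))$p)
  expect_true(all(p_exp < 0.01))
})

test_that("mean confidence intervals match the t quantile and cover", {
  expect_equal(mean_ci(c(1, 1, 1)), list(mean = 1, lo = 1, hi = 1))
  r <- mean_ci(c(0, 2))
  expect_equal(r$mean, 1, tolerance = 1e-12)
  expect_equal(r$hi - r$mean, qt(0.975, 1) * sd(c(0, 2)) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(r$hi - r$mean, 12.7062047, tolerance = 1e-6)

  set.seed(12)
  cover <- mean(replicate(1000, {
    x <- rnorm(30, mean = 5)
    ci <- mean_ci(x)
    ci$lo <= 5 && 5 <= ci$hi
  }))
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("growth rate follows its closed form, shrinkage included", {
  expect_identical(growth_rate(100, 100, 10), 0)
  expect_equal(growth_rate(100, 200, 19), 100 * log(2) / 19,
               tolerance = 1e-12)
  expect_equal(growth_rate(100, 200, 19), 3.648143, tolerance = 1e-6)
  expect_equal(growth_rate(100, 50, 10), -100 * log(2) / 10,
               tolerance = 1e-12)
  expect_equal(growth_rate(100, 120, 10, type = "linear"), 2,
               tolerance = 1e-12)
  expect_error(growth_rate(0, 1, 1), class = "growthtrack_bad_param")
})

test_that("frequency maps count overlaps and conserve mask volume", {
  shape <- c(24, 24, 24)
  aff <- growthtrack:::center_affine(shape)
  a <- sphere_mask(shape, r = 4, center = c(-5, 0, 0), affine = aff)
  b <- sphere_mask(shape, r = 4, center = c(5, 0, 0), affine = aff)
  one <- frequency_map(list(a))
  expect_equal(one$data, a$data)
  two <- frequency_map(list(a, b))
  expect_identical(max(two$data), 1)      # disjoint spheres
  dup <- frequency_map(list(a, a), normalize = TRUE)
  expect_identical(max(dup$data), 2)
  expect_identical(sum(dup$data), 2 * sum(a$data))
  expect_identical(max(attr(dup, "fraction")$data), 1)
})

test_that("cohort summaries aggregate fractions, tests and ANOVAs", {
  set.seed(13)
  mk <- function(id, par, perp, gr, mgmt) {
    mid <- (1 - par - perp) / 5
    bins <- c(par * 0.6, par * 0.4, rep(mid, 5), perp * 0.45, perp * 0.55)
    structure(list(patient_id = id, v1 = 1000, v2 = 1500, interval_days = 20,
                   growth_rate = gr,
                   histogram = angle_histogram(bins, n_voxels = 500L),
                   mgmt = mgmt), class = "patient_result")
  }
  res <- lapply(1:12, function(i)
    mk(paste0("P", i), runif(1, 0.25, 0.4), runif(1, 0.1, 0.2),
       rnorm(1, 2), sample(c("methylated", "unmethylated", "unknown"),
                           1, prob = c(0.45, 0.35, 0.2))))
  s <- summarize_cohort(res)
  expect_identical(s$n, 12L)
  expect_true(s$parallel$lo <= s$parallel$mean &
              s$parallel$mean <= s$parallel$hi)
  expect_equal(s$paired_test$df, 11L)
  expect_true(s$parallel_preference)
  expect_identical(dim(s$bin_means), c(9L, 3L))
  if (!is.null(s$mgmt_anova))
    expect_identical(names(s$mgmt_anova),
                     c("growth_rate", "parallel", "perpendicular"))
})
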
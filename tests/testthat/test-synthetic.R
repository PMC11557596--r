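test_that("a single noiseless domain voxelizes to the analytic sphere volume", {
  ph <- single_sphere_phantom(104)  # 8 voxels diameter
  vol <- ph$volume
  fg <- vol$data >= 0.2
  r_vox <- 104 / 2 / 13
  v_analytic <- 4 / 3 * pi * r_vox^3
  shell <- 4 * pi * r_vox^2  # one-voxel-thick surface shell
  expect_lt(abs(sum(fg) - v_analytic), shell)
})

test_that("generated diameters follow the requested truncated skew-normal", {
  cfg <- phantom_config()
  set.seed(2)
  x <- rskewnorm(5000, cfg$diameter_location, cfg$diameter_scale,
                 cfg$diameter_alpha, lower = cfg$diameter_range[1],
                 upper = cfg$diameter_range[2])
  expect_true(all(x >= 30 & x <= 250))
  lo <- pskewnorm(30, cfg$diameter_location, cfg$diameter_scale, 4)
  hi <- pskewnorm(250, cfg$diameter_location, cfg$diameter_scale, 4)
  cdf <- function(q) {
    (pskewnorm(q, cfg$diameter_location, cfg$diameter_scale, 4) - lo) /
      (hi - lo)
  }
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
  # the default targets a ~80 nm mean
  f <- function(v) v * dskewnorm(v, cfg$diameter_location,
                                 cfg$diameter_scale, 4)
  m_analytic <- stats::integrate(f, 30, 250)$value /
    (hi - lo)
  expect_lt(abs(m_analytic - 80), 2)
  expect_lt(abs(mean(x) - m_analytic), 2 * sd(x) / sqrt(5000))
})

test_that("phantom ground-truth diameters average near the requested mean", {
  cfg <- phantom_config(shape = c(110, 110, 110), n_domains = 150,
                        diameter_range = c(30, 160))
  ph <- generate_phantom(cfg, seed = 3)
  expect_equal(nrow(ph$truth), 150)
  f <- function(v) v * dskewnorm(v, cfg$diameter_location,
                                 cfg$diameter_scale, cfg$diameter_alpha)
  Z <- pskewnorm(160, cfg$diameter_location, cfg$diameter_scale, 4) -
    pskewnorm(30, cfg$diameter_location, cfg$diameter_scale, 4)
  m_analytic <- stats::integrate(f, 30, 160)$value / Z
  se <- sd(ph$truth$diameter_nm) / sqrt(150)
  expect_lt(abs(mean(ph$truth$diameter_nm) - m_analytic), 2 * se + 1)
})

test_that("phantoms are reproducible and fail loudly when over-packed", {
  cfg <- phantom_config(shape = c(48, 48, 48), n_domains = 6)
  p1 <- generate_phantom(cfg, seed = 7)
  p2 <- generate_phantom(cfg, seed = 7)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$truth, p2$truth)
  over <- phantom_config(shape = c(40, 40, 40), n_domains = 500)
  expect_error(generate_phantom(over, seed = 1), "achieved")
})

test_that("dense, surround and background LAC medians are ordered in every realization", {
  for (sd in 1:5) {
    ph <- generate_phantom(phantom_config(shape = c(40, 40, 40),
                                          n_domains = 6), seed = sd)
    seg_med <- median(ph$truth$lac_mean)
    hc_med <- median(ph$volume$data[ph$volume$mask == 2])
    ec_med <- median(ph$volume$data[ph$volume$mask == 1])
    expect_gt(seg_med, hc_med)
    expect_gt(hc_med, ec_med)
  }
})

test_that("feature-table generator spans the null and separable regimes", {
  ft0 <- generate_feature_table(20, effect_size = 0, seed = 1)
  expect_equal(nrow(ft0), 80)
  expect_equal(levels(ft0$label), c("control", "TSA", "G9a", "ROS"))
  r0 <- lda_pipeline(ft0, seed = 3)
  n_test <- sum(r0$projection$split == "test")
  expect_lt(abs(r0$accuracy - 0.25), 4 * sqrt(0.25 * 0.75 / n_test))
  ft10 <- generate_feature_table(20, effect_size = 10, seed = 1)
  r10 <- lda_pipeline(ft10, seed = 3)
  expect_gte(r10$accuracy, 0.95)
  expect_identical(generate_feature_table(10, 1, seed = 4),
                   generate_feature_table(10, 1, seed = 4))
  expect_error(generate_feature_table(10, effect_size = -1), ">= 0")
})

test_that("mask pairs honour the planted transform and frame limits", {
  mp <- generate_mask_pair(c(96, 96), affine2d(1, 0, 0, 0), seed = 1)
  expect_identical(mp$fixed, mp$moving)
  mp2 <- generate_mask_pair(c(128, 128), affine2d(1.2, 30, 4, 4), seed = 1)
  expect_false(identical(mp2$fixed, mp2$moving))
  expect_s3_class(mp2$true_transform, "affine2d")
  # round trip through the registration module
  fit <- register_masks(mp2$fixed, mp2$moving)
  expect_lt(abs(fit$transform$scale - 1.2), 0.02)
  expect_lt(abs(fit$transform$rotation_deg - 30), 1)
})

test_that("TIFF volume round trip preserves LAC data", {
  skip_if_not_installed("tiff")
  ph <- generate_phantom(phantom_config(shape = c(16, 16, 8),
                                        n_domains = 1,
                                        diameter_range = c(30, 60),
                                        diameter_location = 40,
                                        diameter_scale = 5), seed = 1)
  path <- tempfile(fileext = ".tif")
  write_volume_tiff(ph$volume, path)
  back <- read_volume_tiff(path, voxel_nm = 13)
  expect_equal(dim(back$data), c(16, 16, 8))
  expect_equal(back$data, ph$volume$data, tolerance = 1e-6)
})
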
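test_that("domain threshold sits 60% through the LAC range", {
  expect_equal(hmd_threshold(c(0, 1)), 0.6)
  expect_equal(hmd_threshold(c(0.1, 0.25)), 0.19)
  expect_equal(hmd_threshold(runif(100, 0.1, 0.25)),
               0.1 * 0.4 + 0.25 * 0.6, tolerance = 0.01)
  expect_warning(th <- hmd_threshold(rep(0.2, 10)), "constant")
  expect_equal(th, 0.2)
  expect_error(hmd_threshold(numeric(0)))
})

test_that("a single 80 nm sphere is recovered as one domain within a voxel", {
  ph <- single_sphere_phantom(80)
  seg <- segment_domains(ph$volume)
  expect_equal(nrow(seg$domains), 1)
  expect_lt(abs(seg$domains$d_eff_nm - 80), 13)
  expect_lt(abs(seg$domains$x_nm - ph$truth$x_nm), 13)
})

test_that("two spheres fused by a thin neck are split by the watershed", {
  # two 8-voxel-radius spheres whose centres are 13 voxels apart: the
  # overlap forms a neck narrower than either sphere
  d <- c(40, 24, 24)
  arr <- array(0.05, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sph <- function(c0, r) {
    outer(outer((xs - c0[1])^2, (ys - c0[2])^2, "+"), (zs - c0[3])^2,
          "+") <= r^2
  }
  fg <- sph(c(14, 12, 12), 8) | sph(c(27, 12, 12), 8)
  arr[fg] <- 0.25
  vol <- lac_volume(arr, voxel_nm = 13)
  seg <- segment_domains(vol, mask = array(TRUE, d), threshold = 0.2)
  expect_equal(nrow(seg$domains), 2)
})

test_that("an all-background volume yields an empty domain table", {
  vol <- lac_volume(array(0.05, c(16, 16, 16)), 13)
  seg <- segment_domains(vol, mask = array(TRUE, rep(16, 3)),
                         threshold = 0.2)
  expect_equal(nrow(seg$domains), 0)
})

test_that("segmentation labels partition the thresholded foreground", {
  ph <- generate_phantom(phantom_config(shape = c(64, 64, 64),
                                        n_domains = 10,
                                        dense_range = c(0.22, 0.27),
                                        noise_sd = 0), seed = 4)
  seg <- segment_domains(ph$volume, min_voxels = 1)
  fg <- (ph$volume$mask == 2) & (ph$volume$data >= seg$threshold)
  expect_equal(sum(seg$labels > 0), sum(fg))
  expect_equal(sum(seg$domains$n_voxels), sum(fg))
  expect_equal(sum(seg$domains$volume_nm3), sum(fg) * 13^3)
})

test_that("effective diameter inverts sphere volumes and scales with f_mw", {
  expect_equal(effective_diameter(1, 80, 80)$f_mw, 1)
  expect_equal(effective_diameter(pi / 6, 100, 100)$d_eff_nm, 1)
  vol80 <- pi / 6 * 80^3  # 268,083 nm^3
  expect_equal(effective_diameter(vol80, 100, 100)$d_eff_nm, 80)
  # D_eff strictly increasing in V_seg and f_mw
  expect_gt(effective_diameter(2 * vol80, 100, 100)$d_eff_nm, 80)
  expect_gt(effective_diameter(vol80, 120, 100)$d_eff_nm, 80)
  expect_error(effective_diameter(-1, 1, 1))
})

test_that("k-NN distances match brute force and truncate with a warning", {
  pts <- cbind(c(0, 1, 3), 0, 0)
  kk <- knn_distances(pts, k_max = 1)
  expect_equal(as.vector(kk$distances), c(1, 1, 2))
  set.seed(8)
  pts2 <- matrix(rnorm(300), 100, 3)
  kk2 <- knn_distances(pts2, k_max = 10)
  D <- as.matrix(dist(pts2)); diag(D) <- Inf
  brute <- t(apply(D, 1, function(r) sort(r)[1:10]))
  expect_equal(unname(kk2$distances), unname(brute), tolerance = 1e-12)
  expect_true(all(apply(kk2$distances, 1, function(r) !is.unsorted(r))))
  expect_warning(kk3 <- knn_distances(pts2[1:5, ], k_max = 10), "truncat")
  expect_equal(kk3$k_max, 4)
  expect_error(knn_distances(pts2[1, , drop = FALSE]))
})

test_that("coordination number from g(r): closed form, FCC and Poisson", {
  # analytic: g == 1 between r1 and r2 gives (4/3) pi rho (r2^3 - r1^3)
  set.seed(10)
  R <- 20
  pts <- runif_sphere(3000, R)
  rho <- 3000 / (4 / 3 * pi * R^3)
  rz <- domain_rdf_and_zc(pts, R, mean_domain_radius = 1, bin_width = 0.5)
  # Poisson points: whatever r2 is detected, z must match the g==1 form
  if (!rz$no_peak) {
    expect_equal(rz$z, 4 / 3 * pi * rho * (rz$r2^3 - rz$r1^3),
                 tolerance = 0.15)
  }
  # FCC: 12 nearest neighbours
  a <- 2
  fcc <- fcc_points(a, 12)
  nn <- a / sqrt(2)
  rzf <- domain_rdf_and_zc(fcc, 12, mean_domain_radius = nn / 2,
                           bin_width = nn / 6, smooth_half_width = 0)
  expect_false(rzf$no_peak)
  expect_true(rzf$r2 > nn && rzf$r2 < a)
  expect_equal(rzf$z, 12, tolerance = 0.05)
  # oracle: direct neighbour count within the detected shell (bulk points)
  D <- as.matrix(dist(fcc))
  inner <- rowSums(D > 0 & D <= rzf$r2)
  expect_equal(mean(inner[sqrt(rowSums(fcc^2)) < 8]), 12, tolerance = 0.05)
})

test_that("skew-normal fits recover planted shapes and reject degenerate input", {
  set.seed(14)
  x0 <- rnorm(5000)
  f0 <- fit_skew_normal(x0, nboot = 60)
  expect_true(f0$alpha_ci[1] <= 0 && f0$alpha_ci[2] >= 0)
  x4 <- rskewnorm(5000, location = 0, scale = 1, alpha = 4)
  f4 <- fit_skew_normal(x4, nboot = 0)
  expect_lt(abs(f4$alpha - 4) / 4, 0.25)
  expect_error(fit_skew_normal(rep(1, 100)), "degenerate")
  expect_error(fit_skew_normal(rnorm(5)), "at least 20")
})

test_that("per-region LAC summaries respect labels and phantom ranges", {
  ph <- generate_phantom(phantom_config(shape = c(48, 48, 48),
                                        n_domains = 8, noise_sd = 0),
                         seed = 6)
  st <- lac_statistics(ph$volume)
  expect_named(st, c("euchromatin", "heterochromatin"))
  hc <- st$heterochromatin
  expect_gte(hc$min, 0.10 - 1e-9)
  expect_lte(hc$max, 0.27 + 1e-9)
  ec <- st$euchromatin
  expect_gte(ec$min, 0.05 - 1e-9)
  expect_lte(ec$max, 0.22 + 1e-9)
  expect_gt(hc$quantiles[["50%"]], 0)
  # constant region: min = max = mean
  vol <- lac_volume(array(0.2, c(8, 8, 8)), 13)
  labs <- array(2L, c(8, 8, 8))
  s2 <- lac_statistics(vol, labs)
  expect_equal(s2$heterochromatin$min, 0.2)
  expect_equal(s2$heterochromatin$max, 0.2)
  expect_equal(s2$heterochromatin$mean, 0.2)
})

test_that("phantom recovery: many well-separated domains are found with the right sizes", {
  cfg <- phantom_config(shape = c(110, 110, 110), n_domains = 55,
                        dense_range = c(0.22, 0.27), noise_sd = 0.003,
                        diameter_range = c(40, 160))
  ph <- generate_phantom(cfg, seed = 9)
  seg <- segment_domains(ph$volume)
  expect_gte(nrow(ph$truth), 50)
  expect_lt(abs(nrow(seg$domains) - nrow(ph$truth)) / nrow(ph$truth), 0.1)
  expect_lt(abs(mean(seg$domains$d_eff_nm) - mean(ph$truth$diameter_nm)) /
              mean(ph$truth$diameter_nm), 0.1)
})

test_that("z-window cropping clears mask labels outside the depth of field", {
  ph <- generate_phantom(phantom_config(shape = c(24, 24, 24),
                                        n_domains = 2), seed = 2)
  cr <- crop_z_window(ph$volume, 13 * 6, 13 * 18)
  expect_true(all(cr$mask[, , 1:5] == 0))
  expect_true(all(cr$mask[, , 20:24] == 0))
  expect_identical(cr$mask[, , 10], ph$volume$mask[, , 10])
})
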
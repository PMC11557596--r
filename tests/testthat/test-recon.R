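sphere_volume_fixture <- function(n = 32, voxel_nm = 13, lac = 0.2,
                                  radius_nm = 150) {
  xs <- (seq_len(n) - 0.5 - n / 2) * voxel_nm
  r2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  lac_volume(array(lac * (r2 <= radius_nm^2), dim = c(n, n, n)), voxel_nm)
}

test_that("projection of a uniform sphere matches the chord-length map", {
  vol <- sphere_volume_fixture()
  ts <- project_tilt_series(vol, c(-30, 0, 30))
  xs <- (seq_len(32) - 0.5 - 16) * 13
  chord <- outer(xs, xs, function(x, y) {
    d2 <- 150^2 - x^2 - y^2
    ifelse(d2 > 0, 2 * sqrt(pmax(d2, 0)), 0)
  })
  pred <- chord * 0.2 * 1e-3
  obs <- ts$sinogram[, , 2]
  expect_lt(max(abs(obs - pred)) / max(pred), 0.08)
  expect_lt(mean(abs(obs - pred)) / max(pred), 0.01)
  # intensity obeys Beer-Lambert against the sinogram
  expect_equal(ts$intensity, exp(-ts$sinogram), tolerance = 1e-12)
})

test_that("an empty volume projects to a zero sinogram", {
  vol <- lac_volume(array(0, c(16, 16, 16)), 13)
  ts <- project_tilt_series(vol, seq(-60, 60, 10))
  expect_true(all(ts$sinogram == 0))
  expect_true(all(ts$intensity == 1))
})

test_that("mirror-symmetric phantoms project symmetrically at +/- angles", {
  vol <- sphere_volume_fixture(24)
  ts <- project_tilt_series(vol, c(-40, 40))
  # a centred sphere is x-mirror symmetric: p(-theta) = mirror(p(theta))
  m <- ts$sinogram[, , 2][24:1, ]
  expect_equal(ts$sinogram[, , 1], m, tolerance = 1e-8)
})

test_that("forward projector and backprojector are exact adjoints", {
  set.seed(2)
  dims <- c(12, 9, 12)
  ang <- seq(-65, 65, by = 13) * pi / 180
  x <- array(rnorm(prod(dims)), dims)
  Ax <- mesochrom:::project_cpp(as.vector(x), as.integer(dims), ang, 1.0)
  y <- array(rnorm(length(Ax)), dim = dim(Ax))
  Aty <- mesochrom:::backproject_cpp(as.vector(y), as.integer(dims), ang,
                                     1.0)
  expect_lt(abs(sum(Ax * y) - sum(x * Aty)) / abs(sum(Ax * y)), 1e-6)
})

test_that("SIRT reconstructs a full-angle noiseless phantom and decreases its residual", {
  vol <- sphere_volume_fixture()
  ts <- project_tilt_series(vol, seq(-90, 89, by = 3))
  rec <- sirt_reconstruct(ts, n_iterations = 50)
  rng <- diff(range(vol$data))
  expect_lt(sqrt(mean((rec$data - vol$data)^2)) / rng, 0.06)
  res <- attr(rec, "residuals")
  expect_true(all(diff(res) <= 1e-10))
})

test_that("the missing wedge elongates a reconstructed sphere along z", {
  vol <- sphere_volume_fixture()
  ts <- project_tilt_series(vol, seq(-65, 65, by = 3))
  rec <- sirt_reconstruct(ts, n_iterations = 30)
  idx <- which(rec$data >= 0.5 * max(rec$data), arr.ind = TRUE)
  z_extent <- diff(range(idx[, 3]))
  x_extent <- diff(range(idx[, 1]))
  expect_gt(z_extent / x_extent, 1)
})

test_that("an empty tilt series is rejected", {
  vol <- sphere_volume_fixture(16)
  ts <- project_tilt_series(vol, c(0))
  ts$sinogram <- ts$sinogram[, , 0, drop = FALSE]
  ts$angles_deg <- numeric(0)
  expect_error(sirt_reconstruct(ts), "no projections")
})

test_that("FSC of a volume with itself is one at every shell", {
  set.seed(4)
  v <- array(rnorm(16^3), rep(16, 3))
  f <- fsc_resolution(v, v, 13)
  expect_true(all(abs(stats::na.omit(f$shells$fsc) - 1) < 1e-9))
  expect_true(is.na(f$resolution_nm))
})

test_that("the half-set correction maps FSC = 1/3 to 0.5 and is monotone", {
  expect_equal(2 * (1 / 3) / (1 / 3 + 1), 0.5)
  f <- seq(-0.9, 1, by = 0.01)
  corrected <- 2 * f / (f + 1)
  expect_true(all(diff(corrected) > 0))
  # the same mapping as implemented in the shell table
  set.seed(6)
  a <- array(rnorm(12^3), rep(12, 3))
  b <- a + array(rnorm(12^3, 0, 1), rep(12, 3))
  fc <- fsc_resolution(a, b, 13)
  ok <- is.finite(fc$shells$fsc)
  expect_equal(fc$shells$fsc_prime[ok],
               2 * fc$shells$fsc[ok] / (fc$shells$fsc[ok] + 1))
})

test_that("independent noise volumes decorrelate and FSC is symmetric", {
  set.seed(5)
  a <- array(rnorm(24^3), rep(24, 3))
  b <- array(rnorm(24^3), rep(24, 3))
  f <- fsc_resolution(a, b, 13)
  sh <- f$shells[f$shells$k >= 2, ]
  expect_true(all(abs(sh$fsc) < 3 / sqrt(sh$n_voxels / 2), na.rm = TRUE))
  fba <- fsc_resolution(b, a, 13)
  expect_equal(f$shells$fsc, fba$shells$fsc, tolerance = 1e-12)
  expect_error(fsc_resolution(a, b[1:12, , ]), "shapes differ")
})

test_that("even/odd split halves reconstruct and cross-validate end to end", {
  vol <- sphere_volume_fixture(24)
  ts <- project_tilt_series(vol, seq(-65, 65, by = 2))
  halves <- split_even_odd(ts)
  expect_equal(length(halves$even$angles_deg) +
                 length(halves$odd$angles_deg), 66)
  re <- sirt_reconstruct(halves$even, n_iterations = 15, nz = 24)
  ro <- sirt_reconstruct(halves$odd, n_iterations = 15, nz = 24)
  f <- fsc_resolution(re, ro, 13)
  # correlated signal at low frequency
  expect_gt(f$shells$fsc[2], 0.9)
})
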
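# a small hand-built trajectory for exact MSD / overlap checks
make_traj <- function(pos_list, type = NULL, sigma = NULL, dt = 1) {
  n <- nrow(pos_list[[1]])
  if (is.null(type)) type <- rep("A", n)
  if (is.null(sigma)) sigma <- rep(1, n)
  S <- length(pos_list)
  positions <- array(0, dim = c(n, 3, S))
  for (i in seq_len(S)) positions[, , i] <- pos_list[[i]]
  structure(
    list(positions = positions, times = (seq_len(S) - 1) * dt,
         energy_per_bead = rep(0, S), type = type, sigma = sigma,
         cavity_radius = 1e6, params = interaction_params(),
         steady_state = rep(TRUE, S), equilibrated = TRUE,
         warnings = character(), units = unit_system(), seed = 1),
    class = "bd_trajectory")
}

test_that("MSD is zero at zero lag and for a frozen trajectory", {
  frozen <- make_traj(rep(list(matrix(rnorm(30), 10, 3)), 5))
  m <- msd(frozen, "A")
  expect_equal(m$y[m$x == 0], 0)
  expect_true(all(m$y == 0))
  expect_error(msd(frozen, "B"), "no beads")
})

test_that("MSD reproduces a constructed displacement exactly", {
  p0 <- matrix(0, 4, 3)
  p1 <- p0; p1[, 1] <- 2          # every bead moves 2 in x
  p2 <- p0; p2[, 1] <- 3
  m <- msd(make_traj(list(p0, p1, p2)), "A")
  # lag 1: origins (0->1: 4), (1->2: 1) -> mean 2.5 ; lag 2: 9
  expect_equal(m$y, c(0, 2.5, 9))
  expect_equal(m$n, c(4, 8, 4))
})

test_that("overlap function counts a displacement of exactly sigma as moved", {
  p0 <- matrix(0, 2, 3)
  p1 <- p0
  p1[1, 1] <- 1.0   # exactly one diameter: moved (theta(0) = 0)
  p1[2, 1] <- 0.99  # just under: not moved
  q <- overlap_function(make_traj(list(p0, p1)), "A")
  expect_equal(q$y[q$x == 0], 1)
  expect_equal(q$y[q$x == 1], 0.5)
  expect_true(all(q$y >= 0 & q$y <= 1))
})

test_that("overlap decays from one and stays in [0, 1] on a real run", {
  tr <- run_simulation(sim_config(n_beads = 80, n_steps = 1e4,
                                  stride = 500, seed = 13))
  tr <- mark_tail_steady(tr, 0.8)
  q <- overlap_function(tr, "A")
  expect_equal(q$y[1], 1)
  expect_true(all(q$y >= 0 & q$y <= 1))
  # monotone in expectation: allow small fluctuations
  expect_true(mean(diff(q$y) <= 0.02) > 0.9)
})

test_that("confinement-corrected g(r) is flat for uniform points", {
  set.seed(5)
  R <- 10
  pts <- runif_sphere(2000, R)
  edges <- seq(0, R, by = 0.25)
  g <- confined_rdf(pts, R, edges)
  sel <- g$x >= 0.2 * R & g$x <= R
  expect_true(all(abs(g$y[sel] - 1) < 0.1))
  # the naive unbounded-shell normalization is biased low at large r
  gn <- confined_rdf(pts, R, edges, naive = TRUE)
  far <- gn$x >= 0.7 * R & gn$x <= R
  expect_true(all(gn$y[far] < 0.9))
  expect_lt(mean(gn$y[far]), mean(g$y[far], na.rm = TRUE) - 0.2)
})

test_that("two points yield a single occupied bin at their separation", {
  pts <- rbind(c(0, 0, 0), c(1.3, 0, 0))
  g <- confined_rdf(pts, 5, seq(0, 3, by = 0.5))
  expect_equal(which(g$n > 0), 3)  # bin (1.0, 1.5]
  expect_true(all(is.na(g$y[g$n == 0])))
})

test_that("shell volumes integrate to the enclosing sphere volume", {
  R <- 4
  # from the centre and off-centre, the full [0, 2R] shell sweep must
  # recover the sphere volume
  for (d in c(0, 1.7, 3.9)) {
    v <- sum(vapply(seq(0, 2 * R - 0.1, by = 0.1), function(a) {
      mesochrom:::shell_volume(a, a + 0.1, d, R)
    }, numeric(1)))
    expect_equal(v, 4 / 3 * pi * R^3, tolerance = 1e-6)
  }
})

test_that("stretched-exponential fit recovers planted parameters", {
  t <- seq(0.05, 20, by = 0.05)
  y <- exp(-(t / 3)^0.6)
  fit <- fit_stretched_exp(t, y)
  expect_equal(fit$tau_s, 3, tolerance = 0.02)
  expect_equal(fit$beta, 0.6, tolerance = 0.02)
})
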
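test_that("soft-core exclusion has the printed amplitude and cutoff", {
  p <- interaction_params(eps_vex = 10)
  expect_equal(pair_energy(0, "vex", p, "AA"), 10)
  rcut <- p$r_cut_factor * pair_sigma(p, "AA")
  expect_gt(pair_energy(rcut - 1e-9, "vex", p, "AA"), 0)
  expect_identical(pair_energy(rcut + 1e-9, "vex", p, "AA"), 0)
  # mixed-pair width follows sigma_ab = (sigma_A + sigma_B)/2
  sAB <- (p$sigma_A + p$sigma_B) / 2
  expect_equal(pair_energy(0.7, "vex", p, "AB"),
               10 * exp(-4 / sAB^2 * 0.49))
})

test_that("FENE bond energy matches direct evaluation and diverges at r0", {
  p <- interaction_params(fene_k = 1, fene_r0_factor = 1.5, sigma_A = 1)
  expect_equal(pair_energy(0, "fene", p, "AA"), 0)
  # -12 k r0^2 ln(1 - (r/r0)^2) at k = 1, r0 = 1.5, r = 0.75
  expect_equal(pair_energy(0.75, "fene", p, "AA"), 7.7674,
               tolerance = 1e-4)
  expect_identical(pair_energy(1.5, "fene", p, "AA"), Inf)
  expect_identical(pair_energy(2.0, "fene", p, "AA"), Inf)
})

test_that("heterochromatin attraction vanishes at the origin and beyond the cutoff", {
  p <- interaction_params(eps_HC = 3)
  expect_equal(pair_energy(0, "hc", p, "BB"), 0)
  rcut <- p$r_cut_factor * p$sigma_B
  expect_lt(pair_energy(rcut - 1e-6, "hc", p, "BB"), 0)
  expect_identical(pair_energy(rcut + 1e-6, "hc", p, "BB"), 0)
})

test_that("the default HC attraction is minimized at the optimal separation d_B", {
  p <- interaction_params()
  expect_equal(hc_optimal_separation(p, include_vex = FALSE), p$d_B,
               tolerance = 1e-4)
  # with the soft core included the equilibrium separation moves out
  expect_gt(hc_optimal_separation(p, include_vex = TRUE), p$d_B)
})

test_that("wall term is repulsive, truncated and shifted to zero", {
  p <- interaction_params(eps_wall = 1)
  lim <- 2^(1 / 6) * p$sigma_A
  expect_identical(pair_energy(lim + 1e-9, "wall", p, "AA"), 0)
  expect_equal(pair_energy(lim - 1e-12, "wall", p, "AA"), 0,
               tolerance = 1e-9)
  expect_gt(pair_energy(0.8, "wall", p, "AA"), 0)
  expect_true(all(diff(pair_energy(seq(0.5, lim, 0.01), "wall", p,
                                   "AA")) <= 0))
})

test_that("forces are the exact negative gradient of the total energy", {
  set.seed(42)
  p <- interaction_params(eps_HC = 3)
  for (rep in 1:3) {
    st <- build_initial_chain(20, cavity_radius = 3.2, params = p,
                              seed = 50 + rep)
    f <- compute_forces(st, p)
    expect_equal(f$bad_bead, 0)
    h <- 1e-6
    num <- matrix(0, 20, 3)
    for (i in 1:20) for (d in 1:3) {
      sp <- st; sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- st; sm$positions[i, d] <- sm$positions[i, d] - h
      num[i, d] <- -(compute_forces(sp, p)$energy -
                       compute_forces(sm, p)$energy) / (2 * h)
    }
    scale <- max(abs(num), 1)
    expect_lt(max(abs(f$forces - num)) / scale, 1e-5)
  }
})

test_that("symmetric and minimum configurations give zero force", {
  p <- interaction_params()
  # single bead at the cavity centre
  st <- make_state(matrix(0, 1, 3), "A", cavity_radius = 10, params = p)
  f <- compute_forces(st, p)
  expect_equal(max(abs(f$forces)), 0)
  # the bare HC term has zero slope at its numerically located minimum
  rmin <- hc_optimal_separation(p, include_vex = FALSE)
  h <- 1e-6
  slope <- (pair_energy(rmin + h, "hc", p, "BB") -
              pair_energy(rmin - h, "hc", p, "BB")) / (2 * h)
  expect_lt(abs(slope), 1e-4)
  # two bonded B beads at the minimum of their full pair energy
  # (hc + soft core + FENE): zero mutual force
  etot <- function(r) {
    pair_energy(r, "hc", p, "BB") + pair_energy(r, "vex", p, "BB") +
      pair_energy(r, "fene", p, "BB")
  }
  rmin2 <- optimize(etot, c(0.1, p$fene_r0_factor * p$sigma_B - 1e-6))$minimum
  st2 <- make_state(rbind(c(-rmin2 / 2, 0, 0), c(rmin2 / 2, 0, 0)),
                    c("B", "B"), cavity_radius = 50, params = p)
  f2 <- compute_forces(st2, p)
  expect_lt(max(abs(f2$forces)), 1e-3)
})
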
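#' Default confining cavity radius from the reduced number density
#'
#' The cavity radius (reduced units) such that the bead number density is
#' `N/V = density`; the default density 0.2 is the model's working value.
#'
#' @param n_beads chain length.
#' @param density target reduced number density.
#' @return cavity radius in reduced units.
#' @export
cavity_radius_for_density <- function(n_beads, density = 0.2) {
  stopifnot(n_beads > 0, density > 0)
  (3 * n_beads / (4 * pi * density))^(1 / 3)
}

#' Build an initial confined self-avoiding chain
#'
#' Places `n_beads` beads as a random walk inside the spherical cavity with
#' consecutive-bead separations equal to the pair rest length (the pair
#' diameter \eqn{\sigma_{\alpha\beta}}). Because the excluded-volume core is
#' soft, large overlaps between non-consecutive beads are allowed; the walk
#' only avoids immediately re-tracing onto the bead before last. Bead types
#' are assigned by drawing a random permutation of an exact
#' `fraction_A` : `1 - fraction_A` composition.
#'
#' @param n_beads number of beads (>= 2).
#' @param fraction_A fraction of euchromatin (EC/A) beads; default 0.55
#'   giving the model's 55:45 A:B ratio.
#' @param cavity_radius confining radius in reduced units; `NULL` uses
#'   [cavity_radius_for_density()] at density 0.2.
#' @param params an [interaction_params()] (provides bead diameters).
#' @param units a [unit_system()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return an object of class `polymer_state`: list with `positions`
#'   (n x 3), `type` (character "A"/"B"), `sigma` (per-bead reduced
#'   diameter), `cavity_radius`, `units`.
#' @export
build_initial_chain <- function(n_beads, fraction_A = 0.55,
                                cavity_radius = NULL,
                                params = interaction_params(),
                                units = unit_system(), seed = NULL) {
  stopifnot(n_beads >= 2, fraction_A >= 0, fraction_A <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cavity_radius)) cavity_radius <- cavity_radius_for_density(n_beads)
  n_A <- round(n_beads * fraction_A)
  type <- sample(c(rep("A", n_A), rep("B", n_beads - n_A)))
  sigma <- ifelse(type == "A", params$sigma_A, params$sigma_B)
  if (cavity_radius <= max(sigma)) {
    stop("cavity too small to admit the walk")
  }
  max_restarts <- 50L
  max_tries <- 200L
  # keep initial beads outside the WCA wall range so the walk starts
  # force-free at the boundary
  wall_margin <- 2^(1 / 6) * sigma
  for (attempt in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, n_beads, 3)
    # first bead uniform in the admissible sphere
    rmax <- cavity_radius - wall_margin[1]
    repeat {
      p <- stats::runif(3, -rmax, rmax)
      if (sum(p^2) <= rmax^2) break
    }
    pos[1, ] <- p
    ok <- TRUE
    for (i in 2:n_beads) {
      bond <- (sigma[i - 1] + sigma[i]) / 2
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + bond * u
        if (sqrt(sum(cand^2)) > cavity_radius - wall_margin[i]) next
        if (i > 2 &&
            sqrt(sum((cand - pos[i - 2, ])^2)) < 0.5 * sigma[i]) next
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      return(structure(
        list(positions = pos, type = type, sigma = sigma,
             cavity_radius = cavity_radius, units = units),
        class = "polymer_state"))
    }
  }
  stop("placement failure: could not place the walk inside the cavity")
}

#' @export
print.polymer_state <- function(x, ...) {
  cat(sprintf("polymer_state: %d beads (%d A, %d B), cavity radius %.3g sigma_AA\n",
              nrow(x$positions), sum(x$type == "A"), sum(x$type == "B"),
              x$cavity_radius))
  invisible(x)
}

type_code <- function(type) as.integer(type == "B")

#' Forces and potential energy of a polymer state
#'
#' Returns minus the gradient of the total Hamiltonian (pairwise exclusion
#' over all pairs within cutoff, FENE on chain neighbours, heterochromatin
#' attraction on B-B pairs, wall term on every bead) with respect to each
#' bead position.
#'
#' @param state a `polymer_state`.
#' @param params an [interaction_params()].
#' @return list with `forces` (n x 3, reduced units), `energy` (total
#'   potential, \eqn{k_B T}) and `bad_bead` (index of a bead with a
#'   non-finite interaction, 0 if none).
#' @export
compute_forces <- function(state, params = interaction_params()) {
  compute_forces_cpp(state$positions, type_code(state$type), state$sigma,
                     state$cavity_radius, params)
}

#' One Euler-Maruyama step of the overdamped Langevin dynamics
#'
#' Advances the state by
#' \eqn{x \leftarrow x + F/(3\pi\eta\sigma_i)\,dt + \sqrt{2 k_B T\,dt/(3\pi\eta\sigma_i)}\,\xi}
#' with independent standard-normal increments per coordinate. Exposed for
#' testing and stepping small systems; [run_simulation()] drives the same
#' kernel for full trajectories.
#'
#' @param state a `polymer_state`.
#' @param params an [interaction_params()].
#' @param dt timestep in reduced time units (default 1e-4 tau).
#' @param kBT reduced temperature (0 disables noise).
#' @param eta_star reduced viscosity.
#' @return the advanced `polymer_state`.
#' @export
step_euler_maruyama <- function(state, params = interaction_params(),
                                dt = 1e-4, kBT = 1, eta_star = 1) {
  stopifnot(dt > 0)
  res <- bd_run_cpp(state$positions, type_code(state$type), state$sigma,
                    state$cavity_radius, params, dt, 1L, 1L, kBT, eta_star)
  if (res$fail_step >= 0) {
    stop(sprintf("integration failure at step %d (bead %d)",
                 res$fail_step, res$bad_bead))
  }
  state$positions <- matrix(res$snapshots[, , res$n_recorded], ncol = 3)
  state
}

#' Simulation configuration
#'
#' Bundles everything [run_simulation()] needs. The defaults are the scaled
#' working conditions used throughout the package: a 55:45 A:B chain at
#' reduced density 0.2, timestep 1e-4 tau.
#'
#' @param n_beads chain length.
#' @param fraction_A fraction of EC/A beads.
#' @param cavity_radius reduced confining radius; `NULL` from density 0.2.
#' @param params an [interaction_params()].
#' @param dt timestep (tau).
#' @param n_steps total integration steps.
#' @param stride snapshot interval in steps.
#' @param kBT reduced temperature.
#' @param seed integer RNG seed.
#' @param units a [unit_system()].
#' @param equil_tol plateau threshold on |d(energy per bead)/dt| in e/tau.
#' @param state0 optional pre-built `polymer_state` (overrides n_beads etc.).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_beads = 500, fraction_A = 0.55, cavity_radius = NULL,
                       params = interaction_params(), dt = 1e-4,
                       n_steps = 1e5, stride = 1000, kBT = 1, seed = 1,
                       units = unit_system(), equil_tol = 1e-4,
                       state0 = NULL) {
  stopifnot(dt > 0, n_steps >= 1, stride >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Run a Brownian-dynamics trajectory
#'
#' Integrates the overdamped Langevin dynamics from a fresh (or supplied)
#' initial chain, storing snapshots every `stride` steps (the initial and
#' final configurations are always stored). Equilibration is detected from
#' the per-bead potential energy: the trajectory is flagged equilibrated
#' when the linear trend of energy against time is flatter than
#' `equil_tol` e/tau over a trailing window, and snapshots from the
#' earliest such window on are marked steady state. If no plateau is found
#' the steady-state flags are all `FALSE` and a warning record is attached.
#'
#' @param config a [sim_config()].
#' @return an object of class `bd_trajectory`: `positions` (n x 3 x S
#'   array), `times` (tau), `energy_per_bead` (e), `type`, `sigma`,
#'   `cavity_radius`, `params`, `config`, `steady_state` (logical per
#'   snapshot), `equilibrated`, `warnings`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  state <- config$state0
  if (is.null(state)) {
    state <- build_initial_chain(config$n_beads, config$fraction_A,
                                 config$cavity_radius, config$params,
                                 config$units, seed = NULL)
  }
  res <- bd_run_cpp(state$positions, type_code(state$type), state$sigma,
                    state$cavity_radius, config$params, config$dt,
                    as.integer(config$n_steps), as.integer(config$stride),
                    config$kBT, 1)
  if (res$fail_step >= 0) {
    stop(sprintf("integration failure at step %d (bead %d)",
                 res$fail_step, res$bad_bead))
  }
  S <- res$n_recorded
  pos <- array(res$snapshots, dim = c(nrow(state$positions), 3, S))
  times <- res$times[seq_len(S)]
  epb <- res$energy_per_bead[seq_len(S)]
  pl <- detect_plateau(times, epb, config$equil_tol)
  warnings <- character()
  if (!pl$equilibrated) {
    warnings <- "no energy plateau detected within the step budget"
  }
  structure(
    list(positions = pos, times = times, energy_per_bead = epb,
         type = state$type, sigma = state$sigma,
         cavity_radius = state$cavity_radius, params = config$params,
         config = config, steady_state = pl$steady_state,
         equilibrated = pl$equilibrated, warnings = warnings,
         units = config$units, seed = config$seed),
    class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(paste0("bd_trajectory: %d beads, %d snapshots over %.3g tau, ",
                     "eps_HC = %g, equilibrated: %s\n"),
              dim(x$positions)[1], dim(x$positions)[3], max(x$times),
              x$params$eps_HC, x$equilibrated))
  invisible(x)
}

#' Detect the energy plateau of a trajectory
#'
#' Finds the earliest snapshot index from which the linear trend of energy
#' per bead against time stays below `tol` (in e per tau) through the end
#' of the trajectory. The trajectory counts as equilibrated when such an
#' index exists and leaves at least the trailing 20% of the simulated time
#' in the plateau.
#'
#' @param times snapshot times (tau).
#' @param energy_per_bead per-bead potential energy (e).
#' @param tol slope threshold, e/tau.
#' @return list with `equilibrated`, `steady_from` (index or NA) and
#'   `steady_state` (logical vector).
#' @export
detect_plateau <- function(times, energy_per_bead, tol = 1e-4) {
  S <- length(times)
  steady <- rep(FALSE, S)
  if (S < 5) {
    return(list(equilibrated = FALSE, steady_from = NA_integer_,
                steady_state = steady))
  }
  total <- times[S] - times[1]
  steady_from <- NA_integer_
  for (s in seq_len(S - 4)) {
    tt <- times[s:S]
    ee <- energy_per_bead[s:S]
    slope <- stats::cov(tt, ee) / stats::var(tt)
    if (is.finite(slope) && abs(slope) < tol) {
      steady_from <- s
      break
    }
  }
  equilibrated <- !is.na(steady_from) &&
    (times[S] - times[steady_from]) >= 0.2 * total
  if (!is.na(steady_from)) steady[steady_from:S] <- TRUE
  list(equilibrated = equilibrated, steady_from = steady_from,
       steady_state = steady)
}

#' Extract a snapshot as a `polymer_state`
#'
#' @param traj a `bd_trajectory`.
#' @param i snapshot index (1-based); negative counts from the end.
#' @return a `polymer_state`.
#' @export
snapshot_state <- function(traj, i = -1) {
  S <- dim(traj$positions)[3]
  if (i < 0) i <- S + 1 + i
  stopifnot(i >= 1, i <= S)
  structure(
    list(positions = traj$positions[, , i], type = traj$type,
         sigma = traj$sigma, cavity_radius = traj$cavity_radius,
         units = traj$units),
    class = "polymer_state")
}

#' Export a trajectory to XYZ text format
#'
#' One frame per stored snapshot; element column is the bead type.
#'
#' @param traj a `bd_trajectory`.
#' @param path output file.
#' @param steady_only export only steady-state snapshots.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(traj, path, steady_only = FALSE) {
  idx <- seq_len(dim(traj$positions)[3])
  if (steady_only) idx <- idx[traj$steady_state]
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$positions)[1]
  for (i in idx) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %g tau", traj$times[i]), con)
    xyz <- traj$positions[, , i]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$type, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}
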
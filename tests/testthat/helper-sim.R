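# Shared, memoized simulation fixtures. The control-condition runs are the
# scaled study conditions used by the steady-state structure checks:
# N = 500 beads (55:45 A:B), the bead density of a 3000-bead chain in a
# 1 um cavity, eps_HC = 3, dt = 1e-4 tau. They are expensive, so every
# test file reuses the same cached trajectories.

.sim_cache <- new.env(parent = emptyenv())

fig4_density <- function() 3000 / (4 / 3 * pi * (500 / 18)^3)

scaled_cavity_radius <- function(n_beads = 500) {
  (3 * n_beads / (4 * pi * fig4_density()))^(1 / 3)
}

control_runs <- function(n_seeds = 3, n_steps = 3e5, stride = 3000) {
  key <- sprintf("ctrl_%d_%g", n_seeds, n_steps)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    run_simulation(sim_config(
      n_beads = 500, cavity_radius = scaled_cavity_radius(500),
      params = interaction_params(eps_HC = 3),
      n_steps = n_steps, stride = stride, seed = 100 + s))
  })
  .sim_cache[[key]] <- runs
  runs
}

no_affinity_run <- function(n_steps = 1e5, stride = 1000) {
  key <- sprintf("eps0_%g", n_steps)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  run <- run_simulation(sim_config(
    n_beads = 500, cavity_radius = scaled_cavity_radius(500),
    params = interaction_params(eps_HC = 0),
    n_steps = n_steps, stride = stride, seed = 201))
  .sim_cache[[key]] <- run
  run
}

# mark the trailing fraction of snapshots as the measurement window
mark_tail_steady <- function(traj, frac = 0.5) {
  S <- dim(traj$positions)[3]
  traj$steady_state <- seq_len(S) > (1 - frac) * S
  traj
}

tail_snapshots <- function(traj, frac = 0.25) {
  S <- dim(traj$positions)[3]
  seq(ceiling((1 - frac) * S), S)
}

# a hand-built polymer_state for geometric cluster tests
make_state <- function(positions, type, cavity_radius = 100,
                       params = interaction_params()) {
  sigma <- ifelse(type == "A", params$sigma_A, params$sigma_B)
  structure(list(positions = positions, type = type, sigma = sigma,
                 cavity_radius = cavity_radius, units = unit_system()),
            class = "polymer_state")
}
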
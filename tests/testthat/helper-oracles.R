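# Independent oracles used across test files.

# Brute-force cluster oracle: all-pairs bonding, >=3-neighbour core rule,
# BFS connected components over core beads, halo attachment to the
# nearest bonded core bead. Independent of the package implementation
# (no igraph, plain loops).
oracle_clusters <- function(positions, bond_cutoff, min_neighbors = 3,
                            min_size = 4) {
  n <- nrow(positions)
  D <- as.matrix(dist(positions))
  bonded <- D < bond_cutoff
  diag(bonded) <- FALSE
  deg <- rowSums(bonded)
  core <- deg >= min_neighbors
  lab <- integer(n)
  cur <- 0
  for (s in which(core)) {
    if (lab[s] != 0) next
    cur <- cur + 1
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(bonded[v, ] & core & lab == 0)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cn <- which(bonded[i, ] & core)
    if (length(cn)) lab[i] <- lab[cn[which.min(D[i, cn])]]
  }
  keep <- which(tabulate(lab) >= min_size)
  out <- lapply(keep, function(k) sort(which(lab == k)))
  out[order(vapply(out, min, 1L))]
}

# Exact Mann-Whitney U by direct pair counting
oracle_u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# FCC lattice points inside a sphere of radius R (lattice constant a of
# the cubic cell; nearest-neighbour distance a/sqrt(2))
fcc_points <- function(a, R) {
  m <- ceiling(R / a) + 1
  base <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  pts <- do.call(rbind, lapply(seq_len(4), function(o) {
    cbind(base$i + offs[o, 1], base$j + offs[o, 2], base$k + offs[o, 3]) * a
  }))
  pts[rowSums(pts^2) <= R^2, ]
}

# uniform points in a sphere
runif_sphere <- function(n, R) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(runif(3 * n * 2, -R, R), ncol = 3)
    cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), ]
}

# voxelized sphere phantom in a lac_volume, single domain
single_sphere_phantom <- function(diameter_nm = 80, shape = 48,
                                  voxel_nm = 13) {
  generate_phantom(phantom_config(
    shape = rep(shape, 3), voxel_nm = voxel_nm, n_domains = 1,
    diameter_location = diameter_nm, diameter_scale = 1e-3,
    diameter_alpha = 0,
    diameter_range = diameter_nm + c(-1, 1), noise_sd = 0,
    dense_range = c(0.22, 0.27)), seed = 1)
}
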
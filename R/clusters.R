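#' First-minimum bond cutoff from the B-B pair correlation
#'
#' Pools late steady-state snapshots, computes g_BB(r) with the
#' confinement-corrected estimator, and returns the first minimum beyond
#' the principal peak, searched within the nearest-neighbour bond shell
#' (r <= `max_sigma` bead diameters). Pair counts and ideal-gas
#' expectations are pooled over snapshots and smoothed separately before
#' taking their ratio, so near-empty small-r bins (whose raw g is a
#' ratio of two tiny numbers) cannot masquerade as peaks. With very soft
#' cores the clustered phase is an amorphous compressed blob whose g(r)
#' decays without an interior minimum out to the whole-cluster envelope;
#' a minimum found only at that envelope scale is not a bond shell, so
#' the search is capped and the fallback `1.5 * sigma_BB` applies
#' instead.
#'
#' @param traj a `bd_trajectory`.
#' @param bin_width histogram bin width in reduced units.
#' @param max_snapshots cap on the number of pooled snapshots.
#' @param max_sigma bond-shell search limit in units of sigma_BB.
#' @return bond cutoff in reduced units.
#' @export
bond_cutoff_from_rdf <- function(traj, bin_width = 0.05,
                                 max_snapshots = 10, max_sigma = 2) {
  sigBB <- max(traj$sigma)
  idx <- steady_indices(traj)
  # the latest snapshots are the most structured; use the trailing window
  idx <- utils::tail(idx, max_snapshots)
  edges <- seq(0, max_sigma * sigBB, by = bin_width)
  csum <- numeric(length(edges) - 1)
  esum <- numeric(length(edges) - 1)
  for (i in idx) {
    cur <- confined_rdf(traj$positions[, , i], traj$cavity_radius, edges,
                        types = traj$type, pair_kind = "BB")
    csum <- csum + cur$n
    esum <- esum + attr(cur, "expected")
  }
  # kernel-style estimate: smooth counts and expectations, then divide
  g <- smooth3(csum, 3) / pmax(smooth3(esum, 3), 1e-12)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  edge <- first_peak_edge(mid, g, half_width = 0, min_half_width = 3)
  if (is.na(edge)) 1.5 * sigBB else edge
}

# moving-average smoother (default 3-bin), NA-tolerant
smooth3 <- function(y, half_width = 1) {
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    w <- max(1, i - half_width):min(n, i + half_width)
    out[i] <- mean(y[w], na.rm = TRUE)
  }
  out
}

#' Edge of the first peak of a pair-correlation curve
#'
#' Smooths g(r) with a moving average (empty bins count as g = 0),
#' locates the principal peak as the maximum of the smoothed curve, then
#' returns the abscissa of the first minimum beyond it (a point not above
#' any neighbour within `half_width` bins). Minima that dip below the
#' ideal-gas level g = 1 are preferred, so that sampling blips riding on
#' the peak are not mistaken for its edge. `NA` when no peak/minimum
#' structure is detectable.
#'
#' @param r,g curve samples.
#' @param half_width smoothing half width in bins (1 = 3-bin moving
#'   average; 0 disables smoothing, appropriate for clean histograms
#'   whose bins resolve the inter-shell gaps).
#' @param min_half_width neighbourhood half width for the minimum test.
#' @return abscissa of the first-peak edge, or NA.
#' @export
first_peak_edge <- function(r, g, half_width = 1,
                            min_half_width = max(1, half_width)) {
  g0 <- ifelse(is.finite(g), g, 0)
  gs <- if (half_width > 0) smooth3(g0, half_width) else g0
  n <- length(gs)
  peak <- which.max(gs)
  if (gs[peak] <= 1) return(NA_real_)
  if (peak + 1 > n - 1) return(NA_real_)
  is_min <- function(i) {
    w <- max(1, i - min_half_width):min(n, i + min_half_width)
    all(gs[i] <= gs[w])
  }
  cand <- (peak + 1):(n - 1)
  for (i in cand) if (is_min(i) && gs[i] < 1) return(r[i])
  for (i in cand) if (is_min(i)) return(r[i])
  NA_real_
}

#' Identify heterochromatin bead clusters in a snapshot
#'
#' B-B bead pairs closer than `bond_cutoff` are "bonded". Beads with at
#' least `min_neighbors` (default 3) bonded B neighbours are core beads;
#' clusters are the connected components of the bonded graph restricted to
#' core beads. Bonded non-core B beads adjacent to a component ("halo")
#' are attached as members (to the component of their nearest bonded core
#' bead) but not as core; statistics are reported both ways, core+halo
#' being the default membership. Clusters smaller than `min_size` members
#' are discarded.
#'
#' @param state a `polymer_state` (snapshot).
#' @param bond_cutoff bonding distance in reduced units (e.g. from
#'   [bond_cutoff_from_rdf()]; fallback 1.5 sigma_BB).
#' @param min_neighbors bonded-neighbour count that makes a bead core.
#' @param min_size smallest reported cluster (members, core+halo); the
#'   4-bead default matches the smallest-domain argument (a tetrahedron of
#'   B beads).
#' @return an object of class `cluster_set`: lists `members` and `core`
#'   (bead indices into the full chain), vectors `size`, `size_core`,
#'   `diameter_nm`, `diameter_core_nm` (volume-equivalent, from summed
#'   bead volumes), `centroid` (k x 3), plus the inputs needed by
#'   [cluster_coordination()].
#' @export
identify_clusters <- function(state, bond_cutoff = NULL,
                              min_neighbors = 3, min_size = 4) {
  b_idx <- which(state$type == "B")
  sigBB <- if (length(b_idx)) max(state$sigma[b_idx]) else NA_real_
  if (is.null(bond_cutoff)) bond_cutoff <- 1.5 * sigBB
  stopifnot(is.na(sigBB) || bond_cutoff > 0)
  empty <- structure(
    list(members = list(), core = list(), size = integer(0),
         size_core = integer(0), diameter_nm = numeric(0),
         diameter_core_nm = numeric(0),
         centroid = matrix(numeric(0), 0, 3),
         wall_contact = logical(0), adjacency = list(),
         z_c = integer(0), bond_cutoff = bond_cutoff,
         n_beads = length(state$type), sigma_BB = sigBB,
         cavity_radius = state$cavity_radius, units = state$units),
    class = "cluster_set")
  if (length(b_idx) == 0) return(empty)
  P <- state$positions[b_idx, , drop = FALSE]
  nb <- length(b_idx)
  D <- as.matrix(stats::dist(P))
  bonded <- D < bond_cutoff & upper.tri(D)
  bonded <- bonded | t(bonded)
  deg <- rowSums(bonded)
  core <- deg >= min_neighbors
  if (!any(core)) return(empty)
  gcore <- igraph::graph_from_adjacency_matrix(
    bonded[core, core, drop = FALSE], mode = "undirected")
  comp <- igraph::components(gcore)$membership
  lab <- integer(nb)  # 0 = unassigned
  lab[core] <- comp
  # halo attachment: nearest bonded core bead's component
  for (i in which(!core)) {
    cn <- which(bonded[i, ] & core)
    if (length(cn)) lab[i] <- lab[cn[which.min(D[i, cn])]]
  }
  keep <- which(tabulate(lab) >= min_size)
  if (!length(keep)) return(empty)
  sig_nm <- reduced_to_nm(state$sigma, state$units)
  members <- core_m <- vector("list", length(keep))
  size <- size_core <- integer(length(keep))
  dia <- dia_core <- numeric(length(keep))
  centroid <- matrix(0, length(keep), 3)
  wall <- logical(length(keep))
  for (k in seq_along(keep)) {
    m <- which(lab == keep[k])
    cm <- m[core[m]]
    members[[k]] <- b_idx[m]
    core_m[[k]] <- b_idx[cm]
    size[k] <- length(m)
    size_core[k] <- length(cm)
    dia[k] <- sum(sig_nm[b_idx[m]]^3)^(1 / 3)
    dia_core[k] <- sum(sig_nm[b_idx[cm]]^3)^(1 / 3)
    centroid[k, ] <- colMeans(P[m, , drop = FALSE])
    wall[k] <- max(sqrt(rowSums(P[m, , drop = FALSE]^2))) >=
      state$cavity_radius - sigBB
  }
  structure(
    list(members = members, core = core_m, size = size,
         size_core = size_core, diameter_nm = dia,
         diameter_core_nm = dia_core, centroid = centroid,
         wall_contact = wall, adjacency = vector("list", length(keep)),
         z_c = rep(NA_integer_, length(keep)), bond_cutoff = bond_cutoff,
         n_beads = length(state$type), sigma_BB = sigBB,
         cavity_radius = state$cavity_radius, units = state$units),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, mean size %.1f beads, mean D %.1f nm\n",
              length(x$size), mean(x$size), mean(x$diameter_nm)))
  invisible(x)
}

#' Cluster coordination numbers from chain connectivity and wall contacts
#'
#' Two clusters are neighbours when at least one chain segment links a
#' member of one to a member of the other without passing through a third
#' cluster; multiple connecting segments between the same pair are counted
#' once. A cluster whose nearest member bead lies within `sigma_BB` of the
#' cavity wall gains exactly one additional contact.
#'
#' @param cluster_set a `cluster_set` from [identify_clusters()].
#' @return the `cluster_set` with `adjacency` (neighbour lists) and `z_c`
#'   filled in.
#' @export
cluster_coordination <- function(cluster_set) {
  k <- length(cluster_set$members)
  if (k == 0) return(cluster_set)
  bead2cl <- integer(cluster_set$n_beads)
  for (i in seq_len(k)) bead2cl[cluster_set$members[[i]]] <- i
  # chain-ordered sequence of visited clusters, compressed
  visited <- bead2cl[bead2cl != 0]
  visited <- visited[c(TRUE, diff(visited) != 0)]
  adj <- vector("list", k)
  if (length(visited) >= 2) {
    pairs <- unique(t(apply(cbind(visited[-length(visited)], visited[-1]),
                            1, sort)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  cluster_set$adjacency <- lapply(adj, function(v) sort(unique(v)))
  cluster_set$z_c <- vapply(cluster_set$adjacency, length, 1L) +
    as.integer(cluster_set$wall_contact)
  cluster_set
}

#' Cluster statistics over the steady state of a trajectory
#'
#' Identifies clusters (bond cutoff from the first minimum of g_BB unless
#' supplied), computes coordination numbers, and pools per-cluster
#' quantities over steady-state snapshots: size, volume-equivalent
#' diameter (nm), coordination number z_c, and centroid nearest-neighbour
#' separation (nm, snapshots with >= 2 clusters).
#'
#' @param traj a `bd_trajectory`.
#' @param bond_cutoff bonding distance; `NULL` uses
#'   [bond_cutoff_from_rdf()].
#' @param max_snapshots cap on analysed steady-state snapshots.
#' @param snapshots explicit snapshot indices to analyse (overrides the
#'   steady-state selection).
#' @param ... passed to [identify_clusters()].
#' @return list with pooled vectors `size`, `diameter_nm`,
#'   `diameter_core_nm`, `z_c`, `nn_sep_nm`, the per-snapshot cluster
#'   counts `n_clusters`, and `bond_cutoff`.
#' @export
cluster_statistics <- function(traj, bond_cutoff = NULL,
                               max_snapshots = 20, snapshots = NULL, ...) {
  if (is.null(bond_cutoff)) bond_cutoff <- bond_cutoff_from_rdf(traj)
  idx <- if (is.null(snapshots)) steady_indices(traj) else snapshots
  if (length(idx) > max_snapshots) {
    idx <- idx[round(seq(1, length(idx), length.out = max_snapshots))]
  }
  size <- dia <- dia_core <- zc <- nnsep <- numeric(0)
  ncl <- integer(0)
  us <- traj$units
  for (i in idx) {
    cs <- cluster_coordination(
      identify_clusters(snapshot_state(traj, i), bond_cutoff, ...))
    ncl <- c(ncl, length(cs$size))
    if (length(cs$size) == 0) next
    size <- c(size, cs$size)
    dia <- c(dia, cs$diameter_nm)
    dia_core <- c(dia_core, cs$diameter_core_nm)
    zc <- c(zc, cs$z_c)
    if (length(cs$size) >= 2) {
      D <- as.matrix(stats::dist(cs$centroid))
      diag(D) <- Inf
      nnsep <- c(nnsep, reduced_to_nm(apply(D, 1, min), us))
    }
  }
  list(size = size, diameter_nm = dia, diameter_core_nm = dia_core,
       z_c = zc, nn_sep_nm = nnsep, n_clusters = ncl,
       bond_cutoff = bond_cutoff)
}
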
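#' Observable curve container
#'
#' A light data.frame-based container for one-dimensional observables
#' (MSD, overlap function, pair correlation): abscissa `x`, ordinate `y`,
#' per-point sample count `n`, plus `label` and `xlab`/`ylab` attributes.
#' @param x,y,n numeric vectors of equal length.
#' @param label bead type or pair kind the curve refers to.
#' @param xlab,ylab axis descriptions.
#' @keywords internal
observable_curve <- function(x, y, n, label = "", xlab = "x", ylab = "y") {
  stopifnot(length(x) == length(y), length(x) == length(n),
            !is.unsorted(x, strictly = TRUE))
  structure(data.frame(x = x, y = y, n = n),
            label = label, xlab = xlab, ylab = ylab,
            class = c("observable_curve", "data.frame"))
}

steady_indices <- function(traj, steady_only = TRUE) {
  idx <- seq_len(dim(traj$positions)[3])
  if (steady_only && any(traj$steady_state)) idx <- idx[traj$steady_state]
  idx
}

#' Mean squared displacement per bead type
#'
#' Averages the squared displacement over all beads of the given type and
#' over all steady-state time origins (origin averaging improves statistics
#' over a single-origin estimate; the choice is recorded in the curve's
#' attributes).
#'
#' @param traj a `bd_trajectory` with at least two steady-state snapshots.
#' @param bead_type "A" or "B".
#' @param lag_times optional lag times (tau); matched to the nearest
#'   available snapshot lags. `NULL` uses every available lag.
#' @param steady_only restrict to steady-state snapshots.
#' @return an `observable_curve` with `x` = lag (tau), `y` = MSD
#'   (reduced length squared), `n` = number of (origin, bead) samples.
#' @export
msd <- function(traj, bead_type = "A", lag_times = NULL, steady_only = TRUE) {
  beads <- which(traj$type == bead_type)
  if (length(beads) == 0) stop("no beads of type ", bead_type)
  idx <- steady_indices(traj, steady_only)
  if (length(idx) < 2) stop("need at least two steady-state snapshots")
  times <- traj$times[idx]
  dt_snap <- diff(times)[1]
  max_lag <- length(idx) - 1
  lags <- seq_len(max_lag)
  if (!is.null(lag_times)) {
    lags <- sort(unique(pmin(max_lag, pmax(1, round(lag_times / dt_snap)))))
  }
  pos <- traj$positions[beads, , idx, drop = FALSE]
  y <- numeric(length(lags))
  n <- integer(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    orig <- seq_len(length(idx) - L)
    d <- pos[, , orig + L, drop = FALSE] - pos[, , orig, drop = FALSE]
    y[k] <- mean(apply(d^2, c(1, 3), sum))
    n[k] <- length(beads) * length(orig)
  }
  curve <- observable_curve(c(0, lags * dt_snap), c(0, y),
                            c(length(beads), n), label = bead_type,
                            xlab = "lag (tau)", ylab = "MSD (sigma_AA^2)")
  attr(curve, "origin_averaged") <- TRUE
  curve
}

#' Overlap function per bead type
#'
#' Fraction of beads of the given type that have moved less than one
#' bead diameter (type-specific) over the lag; a displacement exactly equal
#' to the diameter counts as moved. Averaged over steady-state time
#' origins.
#'
#' @inheritParams msd
#' @return an `observable_curve` with `y` = Q(t) in [0, 1].
#' @export
overlap_function <- function(traj, bead_type = "A", lag_times = NULL,
                             steady_only = TRUE) {
  beads <- which(traj$type == bead_type)
  if (length(beads) == 0) stop("no beads of type ", bead_type)
  sig <- traj$sigma[beads][1]
  idx <- steady_indices(traj, steady_only)
  if (length(idx) < 2) stop("need at least two steady-state snapshots")
  times <- traj$times[idx]
  dt_snap <- diff(times)[1]
  max_lag <- length(idx) - 1
  lags <- seq_len(max_lag)
  if (!is.null(lag_times)) {
    lags <- sort(unique(pmin(max_lag, pmax(1, round(lag_times / dt_snap)))))
  }
  pos <- traj$positions[beads, , idx, drop = FALSE]
  y <- numeric(length(lags))
  n <- integer(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    orig <- seq_len(length(idx) - L)
    d <- pos[, , orig + L, drop = FALSE] - pos[, , orig, drop = FALSE]
    disp <- sqrt(apply(d^2, c(1, 3), sum))
    y[k] <- mean(sig - disp > 0)  # theta(x) = 1 iff x > 0
    n[k] <- length(beads) * length(orig)
  }
  observable_curve(c(0, lags * dt_snap), c(1, y), c(length(beads), n),
                   label = bead_type, xlab = "lag (tau)", ylab = "Q(t)")
}

# Integral over [a, b] of the area of the r-sphere centred at distance d
# from the centre of the confining R-sphere that lies inside it. Vectorized
# over d.
shell_volume <- function(a, b, d, R) {
  stopifnot(b >= a, a >= 0)
  full_part <- function(r) 4 * pi * r^3 / 3
  cap_part <- function(r, d) {
    (pi / d) * ((R^2 - d^2) * r^2 / 2 + 2 * d * r^3 / 3 - r^4 / 4)
  }
  out <- numeric(length(d))
  small <- d < 1e-12
  if (any(small)) {
    lo <- min(a, R); hi <- min(b, R)
    out[small] <- full_part(hi) - full_part(lo)
  }
  dd <- d[!small]
  if (length(dd)) {
    # full shell for r <= R - d
    lo1 <- pmin(a, pmax(R - dd, 0)); hi1 <- pmin(b, pmax(R - dd, 0))
    v <- full_part(hi1) - full_part(lo1)
    # spherical-cap regime for R - d < r < R + d
    lo2 <- pmax(a, pmax(R - dd, 0)); hi2 <- pmin(b, R + dd)
    ok <- hi2 > lo2
    if (any(ok)) {
      v[ok] <- v[ok] + cap_part(hi2[ok], dd[ok]) - cap_part(lo2[ok], dd[ok])
    }
    out[!small] <- v
  }
  out
}

#' Pair correlation function in spherical confinement
#'
#' Computes g(r) for points in a spherical cavity, normalizing each
#' distance histogram bin by the exact ideal-gas expectation
#' \eqn{\rho \times V_{shell}}, where the shell volume is the analytic
#' intersection of the spherical shell around each reference point with
#' the confining sphere (no periodic images). For unstructured uniform
#' points the estimator returns g = 1 at all r, including near the
#' boundary where a naive \eqn{4\pi r^2 \delta r} normalization is biased
#' low.
#'
#' @param positions n x 3 matrix of points inside the cavity (cavity
#'   centred at the origin).
#' @param cavity_radius confining sphere radius.
#' @param bin_edges increasing vector of bin edges for the separation.
#' @param types optional per-point type vector (e.g. "A"/"B") enabling
#'   pair-kind selection.
#' @param pair_kind "all" or a two-letter pair such as "AA", "AB", "BB"
#'   (requires `types`).
#' @param naive use the unbounded-shell normalization instead (for
#'   demonstrating the confinement bias).
#' @return an `observable_curve` with `x` = bin midpoints, `y` = g(r)
#'   (NA where a bin holds no pairs), `n` = pair counts per bin.
#' @export
confined_rdf <- function(positions, cavity_radius, bin_edges,
                         types = NULL, pair_kind = "all", naive = FALSE) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            all(diff(bin_edges) > 0), all(bin_edges >= 0))
  r_center <- sqrt(rowSums(positions^2))
  if (any(r_center > cavity_radius + 1e-9)) {
    stop("all points must lie inside the cavity")
  }
  if (pair_kind == "all") {
    ref <- tgt <- seq_len(nrow(positions))
  } else {
    stopifnot(!is.null(types), nchar(pair_kind) == 2)
    ab <- strsplit(pair_kind, "")[[1]]
    ref <- which(types == ab[1])
    tgt <- which(types == ab[2])
  }
  if (length(ref) == 0 || length(tgt) == 0) stop("empty reference/target set")
  same <- identical(ref, tgt)
  V <- 4 / 3 * pi * cavity_radius^3
  rho <- (length(tgt) - as.integer(same)) / V
  nb <- length(bin_edges) - 1
  counts <- numeric(nb)
  expected <- numeric(nb)
  d_ref <- r_center[ref]
  # pairwise distances reference -> target, chunked over references
  P <- positions
  chunk <- max(1, floor(2e6 / length(tgt)))
  for (start in seq(1, length(ref), by = chunk)) {
    ii <- ref[start:min(start + chunk - 1, length(ref))]
    d2 <- outer(rowSums(P[ii, , drop = FALSE]^2),
                rowSums(P[tgt, , drop = FALSE]^2), "+") -
      2 * P[ii, , drop = FALSE] %*% t(P[tgt, , drop = FALSE])
    d2[d2 < 0] <- 0
    dist <- sqrt(d2)
    if (same) dist[cbind(seq_along(ii), match(ii, tgt))] <- NA
    counts <- counts + tabulate(
      findInterval(dist[!is.na(dist)], bin_edges,
                   rightmost.closed = TRUE, left.open = TRUE), nb)
  }
  for (k in seq_len(nb)) {
    if (naive) {
      vols <- rep(4 / 3 * pi * (bin_edges[k + 1]^3 - bin_edges[k]^3),
                  length(d_ref))
    } else {
      vols <- shell_volume(bin_edges[k], bin_edges[k + 1], d_ref,
                           cavity_radius)
    }
    expected[k] <- rho * sum(vols)
  }
  g <- counts / expected
  g[counts == 0] <- NA_real_
  mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  out <- observable_curve(mid, g, counts, label = pair_kind,
                          xlab = "r", ylab = "g(r)")
  attr(out, "expected") <- expected
  out
}

#' Power-law exponent of a curve over an abscissa window
#'
#' Least-squares slope of log(y) against log(x) restricted to
#' `x in [x_min, x_max]`; used for the intermediate-lag MSD exponent.
#'
#' @param curve an `observable_curve`.
#' @param x_min,x_max window bounds (inclusive).
#' @return the fitted exponent.
#' @export
loglog_slope <- function(curve, x_min, x_max) {
  sel <- curve$x >= x_min & curve$x <= x_max & curve$x > 0 &
    is.finite(curve$y) & curve$y > 0
  if (sum(sel) < 2) stop("fewer than 2 usable points in window")
  stats::coef(stats::lm(log(curve$y[sel]) ~ log(curve$x[sel])))[[2]]
}

#' Stretched-exponential fit of a decay curve
#'
#' Fits \eqn{y(t) = \exp[-(t/\tau_s)^\beta]} by least squares. A plain
#' curve-fit utility for overlap-function decays; no unit claims are made
#' for the fitted timescale.
#'
#' @param t,y decay curve samples (t > 0 used; y clipped to (0, 1]).
#' @param beta0,tau0 starting values.
#' @return list with `tau_s`, `beta` and the `optim` convergence code.
#' @export
fit_stretched_exp <- function(t, y, beta0 = 0.7, tau0 = NULL) {
  keep <- t > 0 & is.finite(y) & y > 0 & y <= 1
  t <- t[keep]; y <- y[keep]
  if (length(t) < 3) stop("need at least 3 positive samples")
  if (is.null(tau0)) tau0 <- stats::median(t)
  obj <- function(p) {
    tau <- exp(p[1]); beta <- exp(p[2])
    sum((y - exp(-(t / tau)^beta))^2)
  }
  fit <- stats::optim(c(log(tau0), log(beta0)), obj)
  list(tau_s = exp(fit$par[1]), beta = exp(fit$par[2]),
       convergence = fit$convergence)
}
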
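#' Forward-project a LAC volume into a tilt series
#'
#' Parallel-beam line integrals of the LAC volume along the beam axis for
#' each tilt angle (rotation about the y axis, bilinear interpolation,
#' one-voxel ray step). Returns both the sinogram
#' \eqn{-\ln(I/I_0) = \int LAC\,dt} and the transmitted intensity
#' \eqn{I = I_0 \exp(-\int LAC\,dt)}.
#'
#' @param volume a [lac_volume()] (LAC in 1/um).
#' @param angles_deg tilt angles in degrees (strictly increasing, within
#'   +/-90); the default is the acquisition scheme emulated here, -65..65
#'   in 1 degree steps (a 131-projection series with a missing wedge).
#' @param I0 incident intensity.
#' @return an object of class `tilt_series`: `sinogram` (nx x ny x
#'   n_angles array of line integrals, dimensionless), `intensity`,
#'   `angles_deg`, `pixel_nm`, `I0`.
#' @export
project_tilt_series <- function(volume, angles_deg = seq(-65, 65, by = 1),
                                I0 = 1) {
  stopifnot(inherits(volume, "lac_volume"),
            all(abs(angles_deg) <= 90),
            !is.unsorted(angles_deg, strictly = TRUE), I0 > 0)
  d <- dim(volume$data)
  # path lengths in um: voxel step (nm) * 1e-3
  sino <- project_cpp(as.vector(volume$data), as.integer(d),
                      angles_deg * pi / 180, 1.0) * volume$voxel_nm * 1e-3
  structure(list(sinogram = sino, intensity = I0 * exp(-sino),
                 angles_deg = angles_deg, pixel_nm = volume$voxel_nm,
                 I0 = I0), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$sinogram)
  cat(sprintf("tilt_series: %d projections of %d x %d px at %g nm (%g..%g deg)\n",
              d[3], d[1], d[2], x$pixel_nm, min(x$angles_deg),
              max(x$angles_deg)))
  invisible(x)
}

#' SIRT reconstruction of a tilt series
#'
#' Simultaneous iterative reconstruction: starting from zero, each
#' iteration updates the volume with the row- and column-normalized
#' backprojected residual,
#' \eqn{x \leftarrow x + \lambda\,C A^T R (b - A x)}, where `R` and `C`
#' are the inverse row and column sums of the projection weights. The
#' projection residual is monitored and the iteration aborts on
#' divergence (three consecutive residual increases).
#'
#' @param tilt_series a [tilt_series()] (uses the sinogram).
#' @param n_iterations iteration count (>= 1; 20 is the working default).
#' @param nz z extent of the reconstruction (defaults to nx).
#' @param relax relaxation factor \eqn{\lambda}.
#' @param verbose print per-iteration residuals.
#' @return a [lac_volume()] with attribute `residuals` (relative
#'   projection residual per iteration).
#' @export
sirt_reconstruct <- function(tilt_series, n_iterations = 20, nz = NULL,
                             relax = 1, verbose = FALSE) {
  stopifnot(inherits(tilt_series, "tilt_series"), n_iterations >= 1)
  d <- dim(tilt_series$sinogram)
  if (d[3] == 0 || length(tilt_series$angles_deg) == 0) {
    stop("tilt series holds no projections")
  }
  nx <- d[1]; ny <- d[2]
  if (is.null(nz)) nz <- nx
  dims <- as.integer(c(nx, ny, nz))
  ang <- tilt_series$angles_deg * pi / 180
  step_um <- tilt_series$pixel_nm * 1e-3
  b <- tilt_series$sinogram / step_um  # back to voxel-unit path lengths
  A <- function(x) project_cpp(x, dims, ang, 1.0)
  At <- function(p) backproject_cpp(p, dims, ang, 1.0)
  ones_v <- array(1, dims)
  ones_p <- array(1, dim = d)
  rowsum <- A(ones_v); rowsum[rowsum < 1e-6] <- Inf
  colsum <- At(ones_p); colsum[colsum < 1e-6] <- Inf
  x <- array(0, dims)
  res <- numeric(n_iterations)
  b_norm <- sqrt(sum(b^2))
  n_up <- 0
  for (it in seq_len(n_iterations)) {
    r <- b - A(x)
    res[it] <- if (b_norm > 0) sqrt(sum(r^2)) / b_norm else sqrt(sum(r^2))
    if (it >= 2 && res[it] > res[it - 1]) n_up <- n_up + 1 else n_up <- 0
    if (n_up >= 3) {
      stop(sprintf("SIRT diverging: residual grew for 3 consecutive iterations (it %d, residual %.3g)",
                   it, res[it]))
    }
    if (verbose) cat(sprintf("  iter %2d residual %.4g\n", it, res[it]))
    x <- x + relax * At(r / rowsum) / colsum
  }
  out <- lac_volume(x, voxel_nm = tilt_series$pixel_nm)
  attr(out, "residuals") <- res
  out
}

#' Fourier shell correlation and resolution estimate
#'
#' Shell-wise normalized cross-correlation of the Fourier transforms of
#' two independent half-set reconstructions,
#' \deqn{FSC(k) = \Re\sum F G^* / (\sum|F|^2 \sum|G|^2)^{1/2},}
#' with the half-set correction \eqn{FSC' = 2 FSC / (FSC + 1)} and the
#' resolution reported as the half-pitch at the first crossing of the
#' criterion (linear interpolation between shells).
#'
#' @param volume_even,volume_odd equal-shape 3D arrays or [lac_volume()]s.
#' @param voxel_nm voxel size (nm).
#' @param criterion threshold applied to the corrected curve (default
#'   0.5; 0.143 also conventional).
#' @param on apply the criterion to the corrected curve (`"fsc_prime"`)
#'   or the raw one (`"fsc"`).
#' @return an object of class `fsc_curve`: data.frame `shells` with
#'   `k` (shell index), `freq_nm` (1/nm), `fsc`, `fsc_prime`, `n_voxels`;
#'   plus `resolution_nm` (half-pitch, NA if no crossing) and `criterion`.
#' @export
fsc_resolution <- function(volume_even, volume_odd, voxel_nm = 13,
                           criterion = 0.5,
                           on = c("fsc_prime", "fsc")) {
  on <- match.arg(on)
  ve <- if (inherits(volume_even, "lac_volume")) volume_even$data else volume_even
  vo <- if (inherits(volume_odd, "lac_volume")) volume_odd$data else volume_odd
  if (!identical(dim(ve), dim(vo))) stop("volume shapes differ")
  d <- dim(ve)
  Fe <- stats::fft(ve)
  Fo <- stats::fft(vo)
  # integer frequency index per axis with wraparound
  fidx <- function(n) { i <- 0:(n - 1); pmin(i, n - i) }
  kx <- fidx(d[1]); ky <- fidx(d[2]); kz <- fidx(d[3])
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  shell <- round(r)
  kmax <- floor(min(d) / 2)
  num <- Re(Fe * Conj(Fo))
  pe <- Mod(Fe)^2
  po <- Mod(Fo)^2
  sel <- shell <= kmax
  s <- factor(shell[sel], levels = 0:kmax)
  sn <- as.numeric(tapply(num[sel], s, sum, default = 0))
  se <- as.numeric(tapply(pe[sel], s, sum, default = 0))
  so <- as.numeric(tapply(po[sel], s, sum, default = 0))
  nv <- as.numeric(table(s))
  fsc <- sn / sqrt(se * so)
  fsc[!is.finite(fsc)] <- NA
  fscp <- 2 * fsc / (fsc + 1)
  k <- 0:kmax
  n_ext <- max(d)
  freq <- k / (n_ext * voxel_nm)
  y <- if (on == "fsc_prime") fscp else fsc
  resolution <- NA_real_
  for (i in 2:length(k)) {
    if (!is.na(y[i]) && !is.na(y[i - 1]) &&
        y[i - 1] >= criterion && y[i] < criterion) {
      frac <- (y[i - 1] - criterion) / (y[i - 1] - y[i])
      kc <- k[i - 1] + frac * (k[i] - k[i - 1])
      resolution <- n_ext * voxel_nm / (2 * kc)  # half-pitch
      break
    }
  }
  structure(list(shells = data.frame(k = k, freq_nm = freq, fsc = fsc,
                                     fsc_prime = fscp, n_voxels = nv),
                 resolution_nm = resolution, criterion = criterion,
                 on = on, voxel_nm = voxel_nm),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells, criterion %.3g on %s, resolution %s\n",
              nrow(x$shells), x$criterion, x$on,
              if (is.na(x$resolution_nm)) "not reached" else
                sprintf("%.1f nm half-pitch", x$resolution_nm)))
  invisible(x)
}

#' Split a tilt series into even and odd halves
#'
#' Alternate projections by index, yielding two independent half-series
#' for FSC resolution estimation.
#'
#' @param tilt_series a [tilt_series()].
#' @return list of two `tilt_series` (`even`, `odd`).
#' @export
split_even_odd <- function(tilt_series) {
  n <- length(tilt_series$angles_deg)
  pick <- function(sel) {
    structure(list(sinogram = tilt_series$sinogram[, , sel, drop = FALSE],
                   intensity = tilt_series$intensity[, , sel, drop = FALSE],
                   angles_deg = tilt_series$angles_deg[sel],
                   pixel_nm = tilt_series$pixel_nm, I0 = tilt_series$I0),
              class = "tilt_series")
  }
  list(even = pick(seq(1, n, by = 2)), odd = pick(seq(2, n, by = 2)))
}
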
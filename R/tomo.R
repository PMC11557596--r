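#' Mesoscale-domain threshold from the heterochromatin LAC range
#'
#' The segmentation threshold is placed 60% of the way through the LAC
#' range of the (masked) heterochromatin region:
#' \deqn{\Theta_{HMD} = \min(LAC) + 0.6\,(\max(LAC) - \min(LAC))}
#' Raw values within the mask are used (no denoising beforehand).
#'
#' @param lac_values numeric vector (or array) of LAC values of the
#'   heterochromatin region; at least one finite value.
#' @return the threshold (same units as the input).
#' @export
hmd_threshold <- function(lac_values) {
  v <- lac_values[is.finite(lac_values)]
  if (length(v) == 0) stop("no finite LAC values in the region")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant region: threshold equals the constant; downstream segmentation will find no domains")
  }
  rng[1] + 0.6 * (rng[2] - rng[1])
}

#' 3D Euclidean distance transform
#'
#' Distance (voxel units) from each foreground voxel to the nearest
#' background voxel, computed with the separable squared-distance
#' transform; the array border counts as background-adjacent only through
#' real background voxels.
#'
#' @param fg logical 3D array.
#' @return numeric array of distances.
#' @export
distance_transform <- function(fg) {
  stopifnot(is.array(fg), length(dim(fg)) == 3)
  sqrt(edt3d_cpp(as.logical(fg), as.integer(dim(fg))))
}

#' Segment mesoscale domains by threshold + watershed
#'
#' Thresholds the masked heterochromatin region at `threshold`
#' (see [hmd_threshold()]), computes the Euclidean distance transform of
#' the binary foreground, places markers at its local maxima (minimum peak
#' separation `peak_min_sep` voxels), floods a marker watershed, merges
#' basins whose mutual boundary (saddle) distance value reaches
#' `merge_level` of the smaller peak, and discards domains below
#' `min_voxels`.
#'
#' @param volume a [lac_volume()].
#' @param mask logical/integer array selecting the heterochromatin region;
#'   `NULL` uses `volume$mask == 2` if present, else the whole volume.
#' @param threshold LAC threshold; `NULL` computes [hmd_threshold()] on
#'   the masked voxels.
#' @param f_mw missing-wedge factor D_rec/D_fid (see
#'   [effective_diameter()]); rescales z centroids and enters D_eff.
#' @param peak_min_sep minimum marker separation (voxels).
#' @param merge_level saddle/peak ratio above which touching basins merge.
#' @param min_voxels smallest retained domain (voxels).
#' @return list with `labels` (integer array, 0 = background) and
#'   `domains`, a data.frame with per-domain `id`, `n_voxels`,
#'   `volume_nm3` (f_mw-corrected), `d_eff_nm`, centroid `x_nm`, `y_nm`,
#'   `z_nm` (z rescaled by f_mw), `lac_mean`, `lac_max`.
#' @export
segment_domains <- function(volume, mask = NULL, threshold = NULL,
                            f_mw = 1, peak_min_sep = 2, merge_level = 0.8,
                            min_voxels = 8) {
  stopifnot(inherits(volume, "lac_volume"), f_mw > 0)
  lac <- volume$data
  if (is.null(mask)) {
    mask <- if (!is.null(volume$mask)) volume$mask == 2L else
      array(TRUE, dim(lac))
  }
  mask <- mask != 0
  if (is.null(threshold)) threshold <- hmd_threshold(lac[mask])
  fg <- mask & lac >= threshold
  empty <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_nm3 = numeric(0), d_eff_nm = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), lac_mean = numeric(0),
                      lac_max = numeric(0))
  if (!any(fg)) {
    return(list(labels = array(0L, dim(lac)), domains = empty,
                threshold = threshold))
  }
  dt <- distance_transform(fg)
  peaks <- local_maxima_cpp(dt, as.integer(dim(lac)), peak_min_sep)
  if (nrow(peaks) == 0) {
    return(list(labels = array(0L, dim(lac)), domains = empty,
                threshold = threshold))
  }
  labels <- watershed_merge_cpp(dt, fg, as.integer(dim(lac)),
                                peaks[, 4], merge_level,
                                as.integer(min_voxels))
  k <- max(labels)
  if (k == 0) {
    return(list(labels = labels, domains = empty, threshold = threshold))
  }
  vx <- volume$voxel_nm
  idx <- which(labels > 0)
  lab <- labels[idx]
  ai <- arrayInd(idx, dim(lac))
  nvox <- tabulate(lab, k)
  cx <- (vapply(split((ai[, 1] - 0.5) * vx, lab), mean, 1))
  cy <- (vapply(split((ai[, 2] - 0.5) * vx, lab), mean, 1))
  cz <- (vapply(split((ai[, 3] - 0.5) * vx, lab), mean, 1)) * f_mw
  lm <- vapply(split(lac[idx], lab), mean, 1)
  lx <- vapply(split(lac[idx], lab), max, 1)
  vol_nm3 <- nvox * vx^3 * f_mw
  domains <- data.frame(
    id = seq_len(k), n_voxels = nvox, volume_nm3 = vol_nm3,
    d_eff_nm = (6 * vol_nm3 / pi)^(1 / 3),
    x_nm = as.numeric(cx), y_nm = as.numeric(cy), z_nm = as.numeric(cz),
    lac_mean = as.numeric(lm), lac_max = as.numeric(lx))
  list(labels = labels, domains = domains, threshold = threshold)
}

#' Missing-wedge factor and effective domain diameter
#'
#' The missing wedge elongates reconstructed features along z; the factor
#' `f_mw = D_rec / D_fid` (fiducial diameter as reconstructed over its
#' true diameter) corrects segmented volumes, giving the effective
#' diameter \eqn{D_{eff} = (6 f_{mw} V_{seg} / \pi)^{1/3}}.
#'
#' @param V_seg segmented domain volume (nm^3), > 0.
#' @param D_rec fiducial diameter measured in the reconstruction (nm).
#' @param D_fid true fiducial diameter (nm), > 0.
#' @return list with `f_mw` and `d_eff_nm`.
#' @export
effective_diameter <- function(V_seg, D_rec, D_fid) {
  if (any(V_seg <= 0) || any(D_rec <= 0) || any(D_fid <= 0)) {
    stop("V_seg, D_rec and D_fid must be positive")
  }
  f_mw <- D_rec / D_fid
  list(f_mw = f_mw, d_eff_nm = (6 * f_mw * V_seg / pi)^(1 / 3))
}

#' k-nearest-neighbour distances between domain centroids
#'
#' @param centroids n x 3 matrix (nm).
#' @param k_max largest neighbour order (default 10); truncated with a
#'   warning when fewer than `k_max + 1` centroids are available.
#' @return list with `distances` (n x k matrix, column k = distance to the
#'   k-th nearest neighbour), `k_max` actually used, and `pooled` (sorted
#'   vector of all entries, the cumulative pooled distribution).
#' @export
knn_distances <- function(centroids, k_max = 10) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("need at least 2 centroids")
  if (n < k_max + 1) {
    warning(sprintf("only %d centroids: truncating k_max to %d", n, n - 1))
    k_max <- n - 1
  }
  D <- as.matrix(stats::dist(centroids))
  diag(D) <- Inf
  ord <- apply(D, 1, function(r) sort(r)[seq_len(k_max)])
  dists <- t(matrix(ord, nrow = k_max))
  colnames(dists) <- paste0("k", seq_len(k_max))
  list(distances = dists, k_max = k_max, pooled = sort(as.vector(dists)))
}

#' Domain pair correlation and coordination number
#'
#' Computes g(r) for domain centroids with the confinement-corrected
#' estimator, then integrates the first peak to obtain the coordination
#' number
#' \deqn{z = 4\pi\rho_{MD} \int_{r_1}^{r_2} r^2 g(r)\,dr}
#' with \eqn{r_1} the reference-particle radius (by default the mean
#' domain radius) and \eqn{r_2} the first-peak edge, found as the first
#' local minimum of the smoothed g(r) beyond its first maximum.
#'
#' @param centroids n x 3 matrix (nm), n >= 10 for a stable estimate.
#' @param region_radius radius (nm) of the spherical region containing the
#'   centroids (defines the bulk number density and the confinement
#'   correction). The region is re-centred on the centroid mean.
#' @param mean_domain_radius reference-particle radius r1 (nm).
#' @param bin_width histogram bin width (nm); defaults to one 13 nm voxel.
#' @param r_max histogram extent (nm); defaults to the region diameter.
#' @param smooth_half_width smoothing half width (bins) for the
#'   peak-edge search (1 = 3-bin moving average; 0 for clean
#'   histograms).
#' @return an object of class `rdf_result`: `curve` (an
#'   `observable_curve`), `rho_md` (1/nm^3), `r1`, `r2` (nm), `z`
#'   (`NA` with a flag when no first-peak edge is detectable).
#' @export
domain_rdf_and_zc <- function(centroids, region_radius,
                              mean_domain_radius, bin_width = 13,
                              r_max = NULL, smooth_half_width = 1) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 10) warning("fewer than 10 centroids: unstable estimate")
  ctr <- sweep(centroids, 2, colMeans(centroids))
  rad <- max(region_radius, max(sqrt(rowSums(ctr^2))) + 1e-9)
  if (is.null(r_max)) r_max <- 2 * rad
  edges <- seq(0, r_max, by = bin_width)
  curve <- confined_rdf(ctr, rad, edges)
  rho <- n / (4 / 3 * pi * rad^3)
  r1 <- mean_domain_radius
  # restrict the peak search to separations within the region radius;
  # beyond it shell statistics thin out and spurious spikes appear
  inner <- curve$x <= rad
  r2 <- first_peak_edge(curve$x[inner], curve$y[inner],
                        half_width = smooth_half_width)
  z <- NA_real_
  flagged <- TRUE
  if (!is.na(r2) && r2 > r1) {
    # bin-wise quadrature of 4 pi rho r^2 g(r) with the exact shell
    # volume per bin (g constant per bin, empty bins contribute 0), so
    # that the integral reproduces per-reference neighbour counts
    lo <- pmax(edges[-length(edges)], r1)
    hi <- pmin(edges[-1], r2)
    w <- pmax(hi - lo, 0)
    gg <- ifelse(is.finite(curve$y), curve$y, 0)
    z <- 4 * pi * rho * sum((hi^3 - lo^3) / 3 * gg * (w > 0))
    flagged <- FALSE
  }
  structure(list(curve = curve, rho_md = rho, r1 = r1, r2 = r2, z = z,
                 no_peak = flagged), class = "rdf_result")
}

#' Per-region LAC distribution summaries
#'
#' @param volume a [lac_volume()].
#' @param labels integer array of region labels; `NULL` uses
#'   `volume$mask`. Conventional labels: 1 euchromatin,
#'   2 heterochromatin, 3 nucleolus.
#' @param breaks histogram break count.
#' @return named list (per label present) of lists with `n`, `min`,
#'   `max`, `mean`, `sd`, `quantiles` (5%..95%), `hist`.
#' @export
lac_statistics <- function(volume, labels = NULL, breaks = 50) {
  stopifnot(inherits(volume, "lac_volume"))
  if (is.null(labels)) labels <- volume$mask
  if (is.null(labels)) stop("no labels provided and volume carries no mask")
  out <- list()
  region_names <- c("1" = "euchromatin", "2" = "heterochromatin",
                    "3" = "nucleolus")
  for (lv in sort(unique(as.vector(labels[labels > 0])))) {
    v <- volume$data[labels == lv]
    nm <- if (as.character(lv) %in% names(region_names)) {
      region_names[[as.character(lv)]]
    } else {
      paste0("region_", lv)
    }
    out[[nm]] <- list(
      n = length(v), min = min(v), max = max(v), mean = mean(v),
      sd = stats::sd(v),
      quantiles = stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95)),
      hist = graphics::hist(v, breaks = breaks, plot = FALSE))
  }
  out
}
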
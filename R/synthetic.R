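#' Phantom configuration for synthetic LAC volumes
#'
#' Describes a two-phase heterochromatin phantom: dense spherical mesoscale
#' domains (LAC drawn from `dense_range`) embedded in a lower-density
#' heterochromatin surround (`surround_range`), inside a euchromatin
#' background whose voxel values span `background_range` with a left-skewed
#' (beta-shaped) draw so that the region medians order
#' dense > surround > background. Domain diameters follow a truncated
#' skew-normal (defaults give a mean of ~80 nm over a 30-250 nm support).
#'
#' @param shape volume dimensions in voxels (x, y, z).
#' @param voxel_nm voxel edge (nm).
#' @param n_domains number of domains to place.
#' @param diameter_location,diameter_scale,diameter_alpha skew-normal
#'   parameters of the domain-diameter distribution (nm); the defaults
#'   give a truncated mean of ~80 nm.
#' @param diameter_range truncation bounds (nm).
#' @param dense_range,surround_range,background_range LAC ranges (1/um).
#' @param noise_sd additive Gaussian LAC noise (1/um).
#' @param hc_radius_frac heterochromatin region radius as a fraction of the
#'   half-extent of the volume.
#' @param min_gap_nm minimum surface-to-surface clearance between domains.
#' @param overlap_tol fraction of mutual radius overlap tolerated when
#'   placing domains (0 = no overlap).
#' @param z_stretch optional ellipsoidal z-elongation factor applied to the
#'   domains (emulates the missing-wedge artifact; 1 = spheres).
#' @param nucleolus place a nucleolus sphere (label 3) in a corner of the
#'   background.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 96), voxel_nm = 13,
                           n_domains = 40,
                           diameter_location = 56.8, diameter_scale = 30,
                           diameter_alpha = 4,
                           diameter_range = c(30, 250),
                           dense_range = c(0.15, 0.27),
                           surround_range = c(0.10, 0.15),
                           background_range = c(0.05, 0.22),
                           noise_sd = 0.005, hc_radius_frac = 0.85,
                           min_gap_nm = 26, overlap_tol = 0,
                           z_stretch = 1, nucleolus = FALSE) {
  stopifnot(length(shape) == 3, all(shape >= 8), voxel_nm > 0,
            n_domains >= 1, diameter_scale > 0,
            diameter_range[1] > 0,
            diameter_range[2] < min(shape) * voxel_nm,
            noise_sd >= 0, overlap_tol >= 0, overlap_tol < 1,
            z_stretch > 0)
  structure(as.list(environment()), class = "phantom_config")
}

#' Generate a synthetic two-phase LAC phantom
#'
#' Places non-overlapping spherical dense domains inside a spherical
#' heterochromatin region and returns the volume together with the exact
#' ground truth. Reproducible from `seed`.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return list with `volume` (a [lac_volume()] with mask labels
#'   1 = euchromatin, 2 = heterochromatin, 3 = nucleolus) and `truth`
#'   (data.frame: `id`, `x_nm`, `y_nm`, `z_nm`, `diameter_nm`,
#'   `lac_mean`).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  d <- config$shape
  vx <- config$voxel_nm
  extent <- d * vx
  centre <- extent / 2
  hc_r <- config$hc_radius_frac * min(extent) / 2
  # voxel-centre coordinate grids (nm)
  xs <- (seq_len(d[1]) - 0.5) * vx
  ys <- (seq_len(d[2]) - 0.5) * vx
  zs <- (seq_len(d[3]) - 0.5) * vx
  # sample diameters
  dia <- rskewnorm(config$n_domains, config$diameter_location,
                   config$diameter_scale, config$diameter_alpha,
                   lower = config$diameter_range[1],
                   upper = config$diameter_range[2])
  ord <- order(dia, decreasing = TRUE)  # place big domains first
  dia <- dia[ord]
  centres <- matrix(NA_real_, config$n_domains, 3)
  placed <- 0
  max_tries <- 4000
  for (i in seq_len(config$n_domains)) {
    ri <- dia[i] / 2
    rmax <- hc_r - ri * max(1, config$z_stretch) - vx
    done <- FALSE
    if (rmax > 0) {
      for (t in seq_len(max_tries)) {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cand <- centre + u * rmax
        if (placed > 0) {
          prev <- centres[seq_len(placed), , drop = FALSE]
          lim <- (1 - config$overlap_tol) * (ri + dia[seq_len(placed)] / 2) +
            config$min_gap_nm
          if (any(sqrt(rowSums(sweep(prev, 2, cand)^2)) < lim)) next
        }
        placed <- placed + 1
        centres[placed, ] <- cand
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop(sprintf(
        "could not place requested domain count at this density (achieved %d of %d)",
        placed, config$n_domains))
    }
  }
  # region mask: heterochromatin sphere in euchromatin background
  r2grid <- outer(outer((xs - centre[1])^2, (ys - centre[2])^2, "+"),
                  (zs - centre[3])^2, "+")
  mask <- array(1L, dim = d)
  mask[r2grid <= hc_r^2] <- 2L
  # background (euchromatin): left-skewed over its range
  br <- config$background_range
  lac <- array(br[1] + (br[2] - br[1]) * stats::rbeta(prod(d), 2, 5), dim = d)
  # surround (heterochromatin, low-density phase)
  sr <- config$surround_range
  n_hc <- sum(mask == 2L)
  lac[mask == 2L] <- stats::runif(n_hc, sr[1], sr[2])
  # nucleolus: a sphere tucked into the background corner
  if (config$nucleolus) {
    nuc_c <- centre + c(0.72, 0.72, 0) * (min(extent) / 2)
    nuc_r <- 0.18 * min(extent)
    nr2 <- outer(outer((xs - nuc_c[1])^2, (ys - nuc_c[2])^2, "+"),
                 (zs - nuc_c[3])^2, "+")
    sel <- nr2 <= nuc_r^2 & mask == 1L
    mask[sel] <- 3L
    lac[sel] <- stats::runif(sum(sel), 0.12, 0.20)
  }
  # dense domains
  dr <- config$dense_range
  lac_mean <- stats::runif(placed, dr[1], dr[2])
  for (i in seq_len(placed)) {
    ri <- dia[i] / 2
    rz <- ri * config$z_stretch
    ix <- which(abs(xs - centres[i, 1]) <= ri)
    iy <- which(abs(ys - centres[i, 2]) <= ri)
    iz <- which(abs(zs - centres[i, 3]) <= rz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - centres[i, 1])^2 / ri^2
    dy2 <- (ys[iy] - centres[i, 2])^2 / ri^2
    dz2 <- (zs[iz] - centres[i, 3])^2 / rz^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    block <- lac[ix, iy, iz, drop = FALSE]
    block[inside] <- lac_mean[i]
    lac[ix, iy, iz] <- block
  }
  if (config$noise_sd > 0) {
    lac <- lac + array(stats::rnorm(prod(d), 0, config$noise_sd), dim = d)
    lac[lac < 0] <- 0
  }
  truth <- data.frame(id = seq_len(placed),
                      x_nm = centres[, 1], y_nm = centres[, 2],
                      z_nm = centres[, 3], diameter_nm = dia,
                      lac_mean = lac_mean)
  list(volume = lac_volume(lac, voxel_nm = vx, mask = mask), truth = truth)
}

#' Generate a labelled synthetic feature table
#'
#' Emulates the multiparametric per-region feature tables of a four-class
#' perturbation study (control / TSA / G9a / ROS). Informative features
#' receive class-mean shifts of `effect_size` pooled standard deviations
#' in distinct sign patterns per class; the remaining features are pure
#' noise. All features have unit within-class SD.
#'
#' @param n_per_class rows per class (>= 5).
#' @param effect_size class separation in pooled-SD units (>= 0).
#' @param seed integer seed.
#' @param n_features total feature count.
#' @param n_informative number of features carrying class signal.
#' @return a data.frame with a `label` factor, a `batch` id and
#'   `n_features` numeric feature columns.
#' @export
generate_feature_table <- function(n_per_class = 30, effect_size = 1,
                                   seed = 1, n_features = 14,
                                   n_informative = 6) {
  stopifnot(n_per_class >= 5, n_features >= 2,
            n_informative >= 1, n_informative <= n_features)
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)
  classes <- c("control", "TSA", "G9a", "ROS")
  # distinct +/- sign patterns per class over the informative features
  patterns <- rbind(
    rep(c(1, 1), length.out = n_informative),
    rep(c(-1, 1), length.out = n_informative),
    rep(c(1, -1), length.out = n_informative),
    rep(c(-1, -1), length.out = n_informative))
  n <- n_per_class * length(classes)
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  label <- factor(rep(classes, each = n_per_class), levels = classes)
  for (k in seq_along(classes)) {
    rows <- which(label == classes[k])
    X[rows, seq_len(n_informative)] <-
      X[rows, seq_len(n_informative)] +
      matrix(effect_size * patterns[k, ], length(rows), n_informative,
             byrow = TRUE)
  }
  feature_names <- c(
    "domain_count", "foreground_fraction", "lac_mean", "lac_sd",
    "lac_skewness", "deff_mean", "deff_sd", "skewnorm_alpha",
    "knn_mean", "gr_first_peak", "zc_mean", "sphericity_mean",
    "lac_max_mean", "nn1_mean")
  if (n_features <= length(feature_names)) {
    colnames(X) <- feature_names[seq_len(n_features)]
  } else {
    colnames(X) <- c(feature_names,
                     paste0("feature_", seq_len(n_features -
                                                  length(feature_names)) +
                              length(feature_names)))
  }
  cbind(data.frame(label = label,
                   batch = rep(seq_len(2), length.out = n)),
        as.data.frame(X))
}

#' Generate a registration mask pair with known ground truth
#'
#' Rasterizes a smooth star-convex blob as the fixed mask and produces the
#' moving mask by applying a known similarity transform (isotropic scale,
#' rotation, translation) with bilinear anti-aliased re-binarization.
#'
#' @param shape image dimensions (pixels).
#' @param transform an [affine2d()] (fixed -> moving convention).
#' @param seed integer seed controlling the blob shape.
#' @param radius_frac mean blob radius as a fraction of the half-extent.
#' @return list with `fixed`, `moving` (logical matrices) and
#'   `true_transform`.
#' @export
generate_mask_pair <- function(shape = c(128, 128),
                               transform = affine2d(1, 0, 0, 0),
                               seed = 1, radius_frac = 0.55) {
  stopifnot(length(shape) == 2, all(is.finite(unlist(transform[1:4]))))
  set.seed(seed)
  r0 <- radius_frac * min(shape) / 2
  harm <- c(2, 3, 4, 5)
  amp <- stats::runif(4, 0, 0.10)
  # guarantee odd harmonics so the blob is not 180-degree symmetric and
  # the rotation is identifiable
  amp[harm %% 2 == 1] <- stats::runif(sum(harm %% 2 == 1), 0.06, 0.14)
  phase <- stats::runif(4, 0, 2 * pi)
  radius_fun <- function(theta) {
    r <- r0
    for (k in seq_along(harm)) {
      r <- r + r0 * amp[k] * cos(harm[k] * theta + phase[k])
    }
    r
  }
  centre <- shape / 2
  xg <- matrix(seq_len(shape[1]) - 0.5, shape[1], shape[2]) - centre[1]
  yg <- matrix(seq_len(shape[2]) - 0.5, shape[1], shape[2],
               byrow = TRUE) - centre[2]
  theta <- atan2(yg, xg)
  fixed <- sqrt(xg^2 + yg^2) <= radius_fun(theta)
  # moving(p) = fixed(T^{-1}(p)), supersampled 2x for anti-aliasing
  inv <- invert_affine2d(transform)
  sub <- c(-0.25, 0.25)
  acc <- matrix(0, shape[1], shape[2])
  px <- matrix(seq_len(shape[1]) - 0.5, shape[1], shape[2])
  py <- matrix(seq_len(shape[2]) - 0.5, shape[1], shape[2], byrow = TRUE)
  for (dx in sub) for (dy in sub) {
    q <- apply_affine2d(inv, cbind(as.vector(px + dx), as.vector(py + dy)),
                        centre = centre)
    acc <- acc + matrix(bilinear_sample(fixed * 1, q), shape[1], shape[2])
  }
  moving <- acc / 4 >= 0.5
  if (!any(moving) || any(moving[1, ]) || any(moving[shape[1], ]) ||
      any(moving[, 1]) || any(moving[, shape[2]])) {
    stop("transform maps the mask outside the frame")
  }
  list(fixed = fixed, moving = moving, true_transform = transform)
}

# bilinear interpolation of a matrix at points (n x 2), 0 outside;
# pixel-centre convention: centre of pixel i at coordinate i - 0.5
bilinear_sample <- function(img, pts) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pts[, 1] + 0.5  # index coordinate: pixel i sits at x = i
  y <- pts[, 2] + 0.5
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  val <- numeric(nrow(pts))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    w <- (if (di == 1) fx else 1 - fx) * (if (dj == 1) fy else 1 - fy)
    idx <- which(ok & w > 0)
    if (length(idx)) {
      val[idx] <- val[idx] + w[idx] * img[cbind(ii[idx], jj[idx])]
    }
  }
  val
}
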
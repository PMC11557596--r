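#' 2D isotropic affine (similarity) transform
#'
#' A transform of the form \eqn{p' = s R(\theta)(p - c) + c + t}, where `c`
#' is the image centre supplied at application time: isotropic scale `s`,
#' rotation `theta` (degrees, counter-clockwise), translation `(tx, ty)`
#' in pixels.
#'
#' @param scale isotropic scale factor (> 0).
#' @param rotation_deg rotation in degrees.
#' @param tx,ty translation components (pixels).
#' @return an object of class `affine2d`.
#' @export
affine2d <- function(scale = 1, rotation_deg = 0, tx = 0, ty = 0) {
  stopifnot(scale > 0, is.finite(rotation_deg), is.finite(tx), is.finite(ty))
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 tx = tx, ty = ty), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: scale %.4f, rotation %.3f deg, translation (%.3f, %.3f) px\n",
              x$scale, x$rotation_deg, x$tx, x$ty))
  invisible(x)
}

#' Apply, invert and compose 2D similarity transforms
#'
#' @param transform,a,b [affine2d()] objects (`compose_affine2d(a, b)`
#'   applies `b` first, then `a`).
#' @param pts n x 2 matrix of points.
#' @param centre rotation/scaling centre (default the origin).
#' @return transformed points / the inverse or composed `affine2d`.
#' @export
apply_affine2d <- function(transform, pts, centre = c(0, 0)) {
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- sweep(as.matrix(pts), 2, centre)
  out <- transform$scale * p %*% t(R)
  sweep(out, 2, centre + c(transform$tx, transform$ty), "+")
}

#' @rdname apply_affine2d
#' @export
invert_affine2d <- function(transform) {
  th <- -transform$rotation_deg * pi / 180
  s <- 1 / transform$scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_inv <- -s * (R %*% c(transform$tx, transform$ty))
  affine2d(s, -transform$rotation_deg, t_inv[1], t_inv[2])
}

#' @rdname apply_affine2d
#' @export
compose_affine2d <- function(a, b) {
  th <- a$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_ab <- a$scale * (R %*% c(b$tx, b$ty)) + c(a$tx, a$ty)
  affine2d(a$scale * b$scale, a$rotation_deg + b$rotation_deg,
           t_ab[1], t_ab[2])
}

#' Boundary pixels of a binary mask
#'
#' Mask pixels with at least one 4-neighbour outside the mask (or on the
#' image border); returned as pixel-centre coordinates.
#'
#' @param mask logical matrix.
#' @return n x 2 matrix of boundary pixel centres.
#' @export
mask_boundary <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- mask
  interior <- pad[2:(nx + 1), 2:(ny + 1)] &
    pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
    pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
  idx <- which(mask & !interior, arr.ind = TRUE)
  cbind(idx[, 1] - 0.5, idx[, 2] - 0.5)
}

# mean symmetric nearest-neighbour distance between two point sets
boundary_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

# unsigned distance-to-boundary field of a mask (pixels); sampled
# bilinearly this gives a cost smooth in the transform parameters
boundary_distance_field <- function(mask) {
  b <- mask_boundary(mask)
  nx <- nrow(mask); ny <- ncol(mask)
  notb <- matrix(TRUE, nx, ny)
  notb[cbind(b[, 1] + 0.5, b[, 2] + 0.5)] <- FALSE
  d <- sqrt(edt3d_cpp(as.vector(notb), as.integer(c(nx, ny, 1L))))
  matrix(d, nx, ny)
}

#' Register two binary masks with an isotropic affine transform
#'
#' Finds the similarity transform (isotropic scale, rotation, translation)
#' mapping the fixed mask onto the moving mask by minimizing the mean
#' symmetric nearest-neighbour distance between the mask boundaries.
#' Initialization uses mask areas (scale), principal second-moment axes
#' (rotation, both axis polarities tried) and centroids (translation),
#' followed by Nelder-Mead refinement of the boundary-distance cost.
#'
#' @param fixed_mask,moving_mask logical matrices (non-empty, one dominant
#'   component each).
#' @param pixel_size physical pixel size; scales the reported residual.
#' @return list with `transform` (an [affine2d()], fixed -> moving),
#'   `residual` (mean symmetric boundary distance after alignment, in
#'   physical units), and `low_confidence` (TRUE when the residual exceeds
#'   5% of the moving-mask diameter).
#' @export
register_masks <- function(fixed_mask, moving_mask, pixel_size = 1) {
  bf <- mask_boundary(fixed_mask)
  bm <- mask_boundary(moving_mask)
  centre <- c(nrow(fixed_mask) / 2, ncol(fixed_mask) / 2)
  s0 <- sqrt(sum(moving_mask != 0) / sum(fixed_mask != 0))
  ax_angle <- function(pts) {
    p <- sweep(pts, 2, colMeans(pts))
    e <- eigen(stats::cov(p), symmetric = TRUE)
    atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  }
  th0 <- ax_angle(bm) - ax_angle(bf)
  cf <- colMeans(bf); cm <- colMeans(bm)
  Dm <- boundary_distance_field(moving_mask)
  Df <- boundary_distance_field(fixed_mask)
  sample_field <- function(D, pts) {
    # clamp to the field domain; out-of-frame excursions pay their
    # distance to the frame on top of the boundary distance there
    cl <- cbind(pmin(pmax(pts[, 1], 0.5), nrow(D) - 0.5),
                pmin(pmax(pts[, 2], 0.5), ncol(D) - 0.5))
    bilinear_sample(D, cl) + sqrt(rowSums((pts - cl)^2))
  }
  cost <- function(p) {
    tr <- affine2d(exp(p[1]), p[2], p[3], p[4])
    fwd <- sample_field(Dm, apply_affine2d(tr, bf, centre))
    bwd <- sample_field(Df, apply_affine2d(invert_affine2d(tr), bm,
                                           centre))
    (mean(fwd) + mean(bwd)) / 2
  }
  best <- NULL
  for (th in c(th0, th0 + 180)) {
    R <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                  -sin(th * pi / 180), cos(th * pi / 180)), 2, 2)
    t0 <- cm - centre - s0 * (R %*% (cf - centre))
    fit <- stats::optim(c(log(s0), th, t0[1], t0[2]), cost,
                        control = list(maxit = 800, reltol = 1e-10))
    fit <- stats::optim(fit$par, cost,
                        control = list(maxit = 400, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tr <- affine2d(exp(best$par[1]), best$par[2] %% 360,
                 best$par[3], best$par[4])
  if (tr$rotation_deg > 180) tr$rotation_deg <- tr$rotation_deg - 360
  diam <- max(stats::dist(bm[sample(nrow(bm), min(200, nrow(bm))), ]))
  list(transform = tr, residual = best$value * pixel_size,
       low_confidence = best$value > 0.05 * diam)
}
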
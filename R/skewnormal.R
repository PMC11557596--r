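#' Skew-normal density, distribution and sampling
#'
#' Minimal skew-normal machinery used for domain-size distributions:
#' density \eqn{f(x) = (2/\omega)\phi(z)\Phi(\alpha z)} with
#' \eqn{z = (x - \xi)/\omega}, the CDF via Owen's T function (fixed-order
#' Gauss-Legendre quadrature), exact sampling through the two-normal
#' representation, and optional truncation by rejection.
#'
#' @param x,q,n the usual density/CDF/sample arguments.
#' @param location,scale,alpha skew-normal parameters (\eqn{\xi}, \eqn{\omega > 0},
#'   shape \eqn{\alpha}).
#' @param lower,upper optional truncation bounds for [rskewnorm()].
#' @param log return log-density.
#' @return numeric vector.
#' @name skewnormal
NULL

#' @rdname skewnormal
#' @export
dskewnorm <- function(x, location = 0, scale = 1, alpha = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - location) / scale
  ld <- stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE) + log(2) - log(scale)
  if (log) ld else exp(ld)
}

# Owen's T function by 48-node Gauss-Legendre quadrature on [0, a].
owens_t <- function(h, a) {
  if (a == 0) return(numeric(length(h)))
  gl <- statmod_gauss_legendre(48)
  x <- (gl$nodes + 1) / 2 * a
  w <- gl$weights * a / 2
  out <- numeric(length(h))
  for (k in seq_along(x)) {
    out <- out + w[k] * exp(-h^2 * (1 + x[k]^2) / 2) / (1 + x[k]^2)
  }
  out / (2 * pi)
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (base R only).
statmod_gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' @rdname skewnormal
#' @export
pskewnorm <- function(q, location = 0, scale = 1, alpha = 0) {
  stopifnot(scale > 0)
  z <- (q - location) / scale
  stats::pnorm(z) - 2 * owens_t(z, alpha)
}

#' @rdname skewnormal
#' @export
rskewnorm <- function(n, location = 0, scale = 1, alpha = 0,
                      lower = -Inf, upper = Inf) {
  stopifnot(scale > 0, lower < upper)
  delta <- alpha / sqrt(1 + alpha^2)
  draw <- function(m) {
    u0 <- stats::rnorm(m)
    u1 <- stats::rnorm(m)
    location + scale * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
  }
  if (is.infinite(lower) && is.infinite(upper)) return(draw(n))
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- draw(2 * n + 100)
    out <- c(out, x[x >= lower & x <= upper])
    guard <- guard + 1
    if (guard > 1000) stop("truncation bounds reject almost all mass")
  }
  out[seq_len(n)]
}

#' Mean of a skew-normal distribution
#' @inheritParams skewnormal
#' @export
skewnorm_mean <- function(location = 0, scale = 1, alpha = 0) {
  location + scale * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

#' Maximum-likelihood skew-normal fit
#'
#' Fits location, scale and shape by direct likelihood maximization
#' (Nelder-Mead over \eqn{(\xi, \log\omega, \alpha)}, moment-based start),
#' with a bootstrap confidence interval for the shape parameter.
#'
#' @param x numeric sample (n >= 20).
#' @param nboot bootstrap replicates for the shape CI (0 disables).
#' @param conf confidence level.
#' @return list with `location`, `scale`, `alpha`, `alpha_ci`
#'   (NULL when `nboot = 0`), `logLik`, `convergence`.
#' @export
fit_skew_normal <- function(x, nboot = 100, conf = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 20) stop("need at least 20 samples")
  if (stats::sd(x) == 0) stop("degenerate (zero-variance) input")
  fit1 <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    g1 <- mean((x - m)^3) / s^3
    # method-of-moments start for the shape
    g1 <- max(min(g1, 0.95), -0.95)
    r <- sign(g1) * (2 * abs(g1) / (4 - pi))^(1 / 3)
    delta0 <- r / sqrt(2 / pi * (1 + r^2))
    delta0 <- max(min(delta0, 0.99), -0.99)
    a0 <- delta0 / sqrt(1 - delta0^2)
    w0 <- s / sqrt(max(1e-6, 1 - 2 * delta0^2 / pi))
    xi0 <- m - w0 * delta0 * sqrt(2 / pi)
    nll <- function(p) {
      -sum(dskewnorm(x, p[1], exp(p[2]), p[3], log = TRUE))
    }
    opt <- stats::optim(c(xi0, log(w0), a0), nll,
                        control = list(maxit = 2000))
    list(location = opt$par[1], scale = exp(opt$par[2]),
         alpha = opt$par[3], logLik = -opt$value,
         convergence = opt$convergence)
  }
  est <- fit1(x)
  alpha_ci <- NULL
  if (nboot > 0) {
    ab <- vapply(seq_len(nboot), function(b) {
      fit1(sample(x, replace = TRUE))$alpha
    }, numeric(1))
    alpha_ci <- unname(stats::quantile(ab, c((1 - conf) / 2,
                                             1 - (1 - conf) / 2)))
  }
  c(est[c("location", "scale", "alpha")],
    list(alpha_ci = alpha_ci, logLik = est$logLik,
         convergence = est$convergence))
}
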
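#' Interaction parameters for the two-type polymer model
#'
#' Parameters of the four interactions acting in the model: a soft Gaussian
#' "blob" exclusion between all beads, a FENE spring between chain
#' neighbours, an attraction between heterochromatin (HC/B) beads with an
#' optimal separation `d_B`, and a repulsive WCA wall at the spherical
#' confining cavity. All energies are in reduced units of \eqn{e = k_B T},
#' lengths in units of the EC/A bead diameter.
#'
#' Mixed-pair diameters follow the arithmetic rule
#' \eqn{\sigma_{\alpha\beta} = (\sigma_\alpha + \sigma_\beta)/2}. Per-pair
#' derived quantities: `alpha_vex = 4 / sigma_ab^2`, FENE maximum extension
#' `r0 = fene_r0_factor * sigma_ab`, cutoff `r_cut = r_cut_factor * sigma_ab`.
#'
#' The heterochromatin attraction is
#' \deqn{h_{HC}(r) = -\epsilon_{HC}\, r^2 \exp(-\alpha_{HC}[d_B - 1/(\alpha_{HC} d_B) + r^2])}
#' which has its minimum at \eqn{r = 1/\sqrt{\alpha_{HC}}}. The default
#' \eqn{\alpha_{HC} = 1/d_B^2} places the optimal B-B separation exactly at
#' `d_B` (the HC/B bead diameter) and makes the constant term in the
#' exponent cancel, so the default potential is simply
#' \eqn{-\epsilon_{HC} r^2 e^{-r^2/d_B^2}}.
#'
#' @param eps_vex soft-core amplitude (energy units).
#' @param fene_k FENE spring constant (energy / length^2).
#' @param fene_r0_factor FENE maximum extension in units of the pair diameter.
#' @param eps_HC heterochromatin affinity; the regimes of interest are
#'   2 (strongly perturbed), 2.5 (perturbed) and 3 (control).
#' @param alpha_HC width parameter of the HC attraction (1/length^2);
#'   `NULL` uses `1/d_B^2`.
#' @param d_B optimal HC/B separation scale; `NULL` uses `sigma_B`.
#' @param eps_wall WCA wall energy scale.
#' @param r_cut_factor interaction cutoff in units of the pair diameter
#'   (applies to the exclusion and HC attraction).
#' @param sigma_A,sigma_B bead diameters in reduced units (defaults 1 and
#'   25/18, i.e. 18 nm and 25 nm beads).
#' @return an object of class `interaction_params`.
#' @export
interaction_params <- function(eps_vex = 10, fene_k = 1, fene_r0_factor = 1.5,
                               eps_HC = 3, alpha_HC = NULL, d_B = NULL,
                               eps_wall = 1, r_cut_factor = 3,
                               sigma_A = 1, sigma_B = 25 / 18) {
  stopifnot(eps_vex >= 0, eps_HC >= 0, eps_wall >= 0, fene_k > 0,
            fene_r0_factor > 1, r_cut_factor > 0, sigma_A > 0, sigma_B > 0)
  if (is.null(d_B)) d_B <- sigma_B
  if (is.null(alpha_HC)) alpha_HC <- 1 / d_B^2
  stopifnot(d_B > 0, alpha_HC > 0)
  structure(
    list(eps_vex = eps_vex, fene_k = fene_k, fene_r0_factor = fene_r0_factor,
         eps_HC = eps_HC, alpha_HC = alpha_HC, d_B = d_B,
         eps_wall = eps_wall, r_cut_factor = r_cut_factor,
         sigma_A = sigma_A, sigma_B = sigma_B),
    class = "interaction_params")
}

#' Pair diameter for a bead-type pair
#' @param params an [interaction_params()].
#' @param pair one of "AA", "AB", "BA", "BB".
#' @return the arithmetic-mean pair diameter.
#' @export
pair_sigma <- function(params, pair = "AA") {
  s <- c(A = params$sigma_A, B = params$sigma_B)
  ab <- strsplit(pair, "")[[1]]
  stopifnot(length(ab) == 2, all(ab %in% c("A", "B")))
  (s[[ab[1]]] + s[[ab[2]]]) / 2
}

#' Pairwise interaction energies
#'
#' Evaluates one of the model's interaction terms at separations `r`
#' (reduced units). For `kind = "wall"`, `r` is the bead-centre distance
#' from the cavity wall and `pair`'s first letter selects the bead type
#' whose diameter enters the WCA term.
#'
#' * `vex`: \eqn{\epsilon_{vex} e^{-\alpha_{vex} r^2}} for `r <= r_cut`, 0 beyond.
#' * `fene`: \eqn{-12 k r_0^2 \ln[1 - (r/r_0)^2]}; infinite at `r >= r0`.
#' * `hc`: the attraction documented in [interaction_params()], 0 beyond the
#'   BB cutoff.
#' * `wall`: repulsive truncated-shifted Lennard-Jones (WCA),
#'   \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#'   `r <= 2^{1/6} sigma`, 0 beyond.
#'
#' @param r numeric vector of separations (>= 0), reduced units.
#' @param kind one of "vex", "fene", "hc", "wall".
#' @param params an [interaction_params()].
#' @param pair bead-type pair, e.g. "AA", "AB", "BB".
#' @return numeric vector of energies in units of \eqn{k_B T}.
#' @export
pair_energy <- function(r, kind = c("vex", "fene", "hc", "wall"),
                        params = interaction_params(), pair = "AA") {
  kind <- match.arg(kind)
  stopifnot(all(r >= 0))
  sig <- pair_sigma(params, pair)
  rcut <- params$r_cut_factor * sig
  switch(kind,
    vex = {
      a <- 4 / sig^2
      ifelse(r <= rcut, params$eps_vex * exp(-a * r^2), 0)
    },
    fene = {
      r0 <- params$fene_r0_factor * sig
      e <- -12 * params$fene_k * r0^2 * log(pmax(0, 1 - (r / r0)^2))
      e[r >= r0] <- Inf
      e
    },
    hc = {
      sigBB <- params$sigma_B
      rcutBB <- params$r_cut_factor * sigBB
      a <- params$alpha_HC
      cst <- params$d_B - 1 / (a * params$d_B)
      ifelse(r <= rcutBB,
             -params$eps_HC * r^2 * exp(-a * (cst + r^2)), 0)
    },
    wall = {
      si <- pair_sigma(params, paste0(substr(pair, 1, 1), substr(pair, 1, 1)))
      out <- numeric(length(r))
      act <- r <= 2^(1 / 6) * si & r > 0
      sr6 <- (si / r[act])^6
      out[act] <- 4 * params$eps_wall * (sr6^2 - sr6) + params$eps_wall
      out[r == 0] <- Inf
      out
    })
}

#' Separation minimizing the heterochromatin pair energy
#'
#' Locates the minimum of the combined B-B pair energy (or of the HC term
#' alone) numerically.
#'
#' @param params an [interaction_params()].
#' @param include_vex also include the soft-core exclusion (the physical
#'   B-B pair energy); `FALSE` minimizes the bare HC term.
#' @return the separation (reduced units) at the energy minimum.
#' @export
hc_optimal_separation <- function(params = interaction_params(),
                                  include_vex = TRUE) {
  f <- function(r) {
    e <- pair_energy(r, "hc", params, "BB")
    if (include_vex) e <- e + pair_energy(r, "vex", params, "BB")
    e
  }
  rcut <- params$r_cut_factor * params$sigma_B
  stats::optimize(f, interval = c(1e-6, rcut))$minimum
}
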
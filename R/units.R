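#' Boltzmann constant in pN nm / K
#'
#' CODATA value 1.380649e-23 J/K expressed in pN nm per kelvin.
#' @keywords internal
KB_PN_NM_PER_K <- 1.380649e-2

#' Reduced unit system for the confined polymer model
#'
#' The simulation works in reduced units: the euchromatin (EC/A) bead
#' diameter is the unit of length, the thermal energy \eqn{e = k_B T} the
#' unit of energy, and the nucleoplasmic viscosity the unit of viscosity
#' (\eqn{\eta^* = 1}). The unit of time follows as
#' \eqn{\tau = \eta \sigma_{AA}^3 / (\eta^* e)}.
#'
#' At the defaults (T = 310 K, \eqn{\eta} = 1.5 cP, \eqn{\sigma_{AA}} = 18 nm)
#' the energy unit is 4.28 pN nm and \eqn{\tau \approx 2.04e-3} ms. The time
#' unit can be overridden via `time_unit_ms` for users who prefer a different
#' calibration.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @param viscosity_cP nucleoplasmic viscosity in centipoise.
#' @param sigma_AA_nm EC/A bead diameter in nm (the reduced length unit).
#' @param reduced_viscosity viscosity in reduced units (conventionally 1).
#' @param time_unit_ms reduced time unit in ms; `NULL` derives it from the
#'   formula above.
#' @return an object of class `unit_system` with fields `temperature_K`,
#'   `energy_unit_pNnm`, `viscosity_cP`, `sigma_AA_nm`, `time_unit_ms`,
#'   `reduced_viscosity`.
#' @examples
#' us <- unit_system()
#' us$energy_unit_pNnm  # 4.28 pN nm at 310 K
#' @export
unit_system <- function(temperature_K = 310, viscosity_cP = 1.5,
                        sigma_AA_nm = 18, reduced_viscosity = 1,
                        time_unit_ms = NULL) {
  stopifnot(temperature_K > 0, viscosity_cP > 0, sigma_AA_nm > 0,
            reduced_viscosity > 0)
  e_pNnm <- KB_PN_NM_PER_K * temperature_K
  if (is.null(time_unit_ms)) {
    # eta [Pa s] * sigma^3 [m^3] / e [J] -> seconds -> ms
    eta_Pas <- viscosity_cP * 1e-3
    sigma_m <- sigma_AA_nm * 1e-9
    e_J <- e_pNnm * 1e-21
    time_unit_ms <- eta_Pas * sigma_m^3 / (reduced_viscosity * e_J) * 1e3
  }
  structure(
    list(temperature_K = temperature_K,
         energy_unit_pNnm = e_pNnm,
         viscosity_cP = viscosity_cP,
         sigma_AA_nm = sigma_AA_nm,
         reduced_viscosity = reduced_viscosity,
         time_unit_ms = time_unit_ms),
    class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced unit system\n")
  cat(sprintf("  T          = %g K\n", x$temperature_K))
  cat(sprintf("  e = kB T   = %.4g pN nm\n", x$energy_unit_pNnm))
  cat(sprintf("  sigma_AA   = %g nm\n", x$sigma_AA_nm))
  cat(sprintf("  eta        = %g cP (eta* = %g)\n", x$viscosity_cP,
              x$reduced_viscosity))
  cat(sprintf("  tau        = %.4g ms\n", x$time_unit_ms))
  invisible(x)
}

#' Convert between reduced and physical units
#'
#' Round-trippable scalar conversions for length (nm), time (ms) and
#' energy (pN nm).
#'
#' @param x numeric vector in reduced units (or physical units for the
#'   `*_to_reduced` directions).
#' @param us a [unit_system()].
#' @return numeric vector.
#' @export
reduced_to_nm <- function(x, us) x * us$sigma_AA_nm

#' @rdname reduced_to_nm
#' @export
nm_to_reduced <- function(x, us) x / us$sigma_AA_nm

#' @rdname reduced_to_nm
#' @export
reduced_to_ms <- function(x, us) x * us$time_unit_ms

#' @rdname reduced_to_nm
#' @export
ms_to_reduced <- function(x, us) x / us$time_unit_ms

#' @rdname reduced_to_nm
#' @export
reduced_to_pNnm <- function(x, us) x * us$energy_unit_pNnm

#' @rdname reduced_to_nm
#' @export
pNnm_to_reduced <- function(x, us) x / us$energy_unit_pNnm

#' Nucleosome content of a coarse-grained bead
#'
#' A bead of diameter `d_bead_nm` contains approximately
#' `(d_bead_nm / d_nucleosome_nm)^3` nucleosomes (volumetric scaling with a
#' 10 nm nucleosome). The 25 nm heterochromatin bead maps to 16 nucleosomes
#' (~3 kbp), the 18 nm euchromatin bead to ~6 nucleosomes (~1.2 kbp).
#'
#' @param d_bead_nm bead diameter in nm.
#' @param d_nucleosome_nm nucleosome diameter in nm.
#' @return number of nucleosomes (unrounded).
#' @export
nucleosomes_per_bead <- function(d_bead_nm, d_nucleosome_nm = 10) {
  stopifnot(d_bead_nm > 0, d_nucleosome_nm > 0)
  (d_bead_nm / d_nucleosome_nm)^3
}
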
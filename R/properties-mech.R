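# Pseudo-viscoelastic water/ice viscosity and Type-316 steel property fits.

#' Pseudo-viscosity of the water/ice continuum
#'
#' Logistic blend \eqn{\eta(T,P) = f \eta_l + (1-f)\eta_s} between the liquid
#' value \eqn{\eta_l = 10^4} Pa s and the solid value \eqn{\eta_s = 10^{14}}
#' Pa s. The ten-order-of-magnitude jump across the 1 K transition band makes
#' the solid phase behave linear-elastically on any practical time scale
#' (Maxwell relaxation time \eqn{\eta_s/G \sim} hours) while the liquid
#' relaxes deviatoric stress in microseconds, so a single Maxwell continuum
#' spans both phases without front tracking.
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @param eta_l,eta_s Liquid and solid pseudo-viscosities in Pa s.
#' @param a0 Logistic steepness in 1/K.
#' @return Viscosity in Pa s.
#' @export
pseudo_viscosity <- function(T, P_gauge = 0, eta_l = 1e4, eta_s = 1e14,
                             a0 = 9.19) {
  f <- phase_fraction(T, P_gauge, a0)
  f * eta_l + (1 - f) * eta_s
}

#' Water-domain elastic constants
#'
#' Constant elastic modulus (10 GPa) and Poisson ratio (0.33) assumed
#' temperature- and pressure-independent throughout the water/ice domain.
#'
#' @return Named list with `E` (Pa), `nu`, `eta_l`, `eta_s` (Pa s).
#' @export
water_mechanical_properties <- function() {
  list(E = 10e9, nu = 0.33, eta_l = 1e4, eta_s = 1e14)
}

.steel_fits <- list(
  density = function(T)
    (((-1.338e-10 * T + 4.114e-7) * T - 4.831e-4) * T - 1.964e-1) * T +
      8.058e3,
  conductivity = function(T)
    (((-1.241e-12 * T + 6.271e-10) * T - 4.707e-6) * T + 2.084e-2) * T +
      7.956,
  specific_heat = function(T)
    ((2.027e-5 * T - 1.649e-2) * T + 5.007) * T - 75.58,
  elastic_modulus = function(T)
    (((-3.652 * T + 3.231e3) * T - 1.091e6) * T + 9.297e7) * T + 2.059e11,
  poisson = function(T) rep_len(0.29, length(T)),
  expansion = function(T)
    ((5.046e-14 * T - 6.456e-11) * T + 3.204e-8) * T + 1.102e-5
)

#' Type-316 stainless-steel properties
#'
#' Polynomial fits of the chamber-wall material properties versus temperature,
#' evaluated as published: density (kg/m^3), thermal conductivity (W/m K),
#' specific heat (J/kg K), elastic modulus (Pa), Poisson ratio
#' (constant 0.29), and linear thermal expansion coefficient (1/K).
#'
#' @param name One of `"density"`, `"conductivity"`, `"specific_heat"`,
#'   `"elastic_modulus"`, `"poisson"`, `"expansion"`.
#' @param T Temperature in K, in \[230, 320\].
#' @return Property value in SI units.
#' @export
#' @examples
#' steel_property("conductivity", 293.15)  # about 13.7 W/m K
steel_property <- function(name, T) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.steel_fits))
    stop("unknown steel property; expected one of: ",
         paste(names(.steel_fits), collapse = ", "), call. = FALSE)
  if (any(!is.finite(T)) || any(T < 230) || any(T > 330))
    stop("steel property fits are valid on [230, 330] K", call. = FALSE)
  .steel_fits[[name]](T)
}
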
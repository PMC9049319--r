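# Thermal conductivity and specific heat fits for liquid water and ice Ih.
# All fits take the adjusted temperature (atmospheric-referenced, shifted by
# the melting-point suppression) in K and return SI units.

#' Thermal conductivity and specific heat of the pure phases
#'
#' Atmospheric-pressure fits evaluated at the adjusted temperature
#' \eqn{T_{adj} = T - T_{sup}(P)}: elevated pressure shifts the temperature
#' scale by the melting-point suppression but leaves the shape of each fit
#' unchanged. Liquid conductivity is a cubic, liquid specific heat a quartic,
#' ice conductivity an exponential decay and ice specific heat a linear fit.
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa (enters only through the adjusted
#'   temperature).
#' @return Conductivity in W/(m K) or specific heat in J/(kg K).
#' @name pure_phase_thermal
NULL

#' @rdname pure_phase_thermal
#' @export
conductivity_liquid <- function(T, P_gauge = 0) {
  Ta <- adjusted_temperature(T, P_gauge)
  ((7.975e-9 * Ta - 1.583e-5) * Ta + 8.949e-3) * Ta - 8.691e-1
}

#' @rdname pure_phase_thermal
#' @export
specific_heat_liquid <- function(T, P_gauge = 0) {
  Ta <- adjusted_temperature(T, P_gauge)
  (((3.625e-7 * Ta - 5.382e-4) * Ta + 3.099e-1) * Ta - 80.41) * Ta + 1.201e4
}

#' @rdname pure_phase_thermal
#' @export
conductivity_ice <- function(T, P_gauge = 0) {
  Ta <- adjusted_temperature(T, P_gauge)
  9.828 * exp(-5.7e-3 * Ta)
}

#' @rdname pure_phase_thermal
#' @export
specific_heat_ice <- function(T, P_gauge = 0) {
  Ta <- adjusted_temperature(T, P_gauge)
  1.523e2 + 7.116 * Ta
}

#' Mixture thermal conductivity across the phase-transition band
#'
#' Logistic blend \eqn{k_m = f k_l + (1-f) k_s} of the pure-phase
#' conductivities, continuous through the transition band, reducing exactly to
#' the pure-phase value where `f` is 0 or 1.
#'
#' @inheritParams pure_phase_thermal
#' @param a0 Logistic steepness in 1/K.
#' @return Conductivity in W/(m K).
#' @export
mixture_conductivity <- function(T, P_gauge = 0, a0 = 9.19) {
  f <- phase_fraction(T, P_gauge, a0)
  f * conductivity_liquid(T, P_gauge) + (1 - f) * conductivity_ice(T, P_gauge)
}

#' Apparent (mixture) specific heat with the latent-heat term
#'
#' The enthalpy-method specific heat
#' \eqn{C_{p,m} = f C_{p,l} + (1-f) C_{p,s} + L(T_m)\, df/dT}: the logistic
#' blend of the pure-phase sensible heats plus the latent heat of fusion
#' released at the local phase-transition rate. The latent term peaks at
#' \eqn{L a_0 / 4} at the melting temperature and integrates to \eqn{L(T_m)}
#' across the transition band, so the method conserves energy.
#'
#' @inheritParams mixture_conductivity
#' @param latent A [latent_model()]; set `include_latent = FALSE` to obtain
#'   the sensible blend only.
#' @param include_latent Logical; include the latent-heat term?
#' @return Apparent specific heat in J/(kg K).
#' @export
mixture_specific_heat <- function(T, P_gauge = 0, latent = latent_model(),
                                  a0 = 9.19, include_latent = TRUE) {
  f <- phase_fraction(T, P_gauge, a0)
  cp <- f * specific_heat_liquid(T, P_gauge) +
    (1 - f) * specific_heat_ice(T, P_gauge)
  if (include_latent) {
    Tm <- melting_temperature(P_gauge)
    cp <- cp + latent_heat(Tm, latent) * (a0 * f * (1 - f))
  }
  cp
}
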
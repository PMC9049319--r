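#' @keywords internal
"_PACKAGE"

# Liquidus polynomial coefficients, gauge pressure in Pa -> K.
.liq_c3 <- -5.701e-25
.liq_c2 <- 5.892e-18
.liq_c1 <- -8.363e-8
.liq_c0 <- 273.2

# Model domain limits (gauge Pa, K). The liquidus of ice Ih terminates at the
# liquid/ice-Ih/ice-III triple point (~-22 C, 207.4 MPa); a small margin is
# allowed above it so root-finding brackets stay open.
.P_MAX <- 2.12e8
.T_TRIPLE <- 251.15
.T_MELT_ATM <- 273.2

#' Pressure-dependent melting temperature of ice Ih
#'
#' Evaluates the cubic liquidus fit of the ice-Ih melting line,
#' \eqn{T_m(P) = -5.701\times10^{-25}P^3 + 5.892\times10^{-18}P^2 -
#' 8.363\times10^{-8}P + 273.2} K, with `P` the gauge pressure in Pa.
#' The fit is strictly decreasing over the model domain and spans 273.2 K at
#' atmospheric pressure down to about 251 K (-22 C) at the liquid/ice-Ih/ice-III
#' triple point.
#'
#' @param P_gauge Gauge pressure in Pa (pressure above standard atmospheric),
#'   vectorized. Must lie in \[0, 2.12e8\].
#' @return Melting temperature in K.
#' @seealso [liquidus_pressure()] for the inverse.
#' @export
#' @examples
#' melting_temperature(0)        # 273.2 K
#' melting_temperature(207.4e6)  # about 251 K (-22 C)
melting_temperature <- function(P_gauge) {
  if (any(!is.finite(P_gauge)) || any(P_gauge < 0) || any(P_gauge > .P_MAX)) {
    stop("gauge pressure outside the liquidus model domain [0, 2.12e8] Pa",
         call. = FALSE)
  }
  ((.liq_c3 * P_gauge + .liq_c2) * P_gauge + .liq_c1) * P_gauge + .liq_c0
}

#' Liquidus (equilibrium freezing) pressure at a given temperature
#'
#' Inverts the melting-temperature polynomial by bracketed root finding on
#' \[0, 2.1e8\] Pa. The round trip
#' `melting_temperature(liquidus_pressure(T))` recovers `T` to better than
#' 1e-6 K.
#'
#' @param T Temperature in K, vectorized. Must lie in \[251.15, 273.2\] K
#'   (between the ice-Ih/ice-III triple point and the atmospheric melting
#'   point).
#' @return Gauge pressure in Pa at which ice Ih and liquid water coexist.
#' @export
#' @examples
#' liquidus_pressure(263.15) / 1e6  # about 111 MPa at -10 C
liquidus_pressure <- function(T) {
  if (any(!is.finite(T)) || any(T < .T_TRIPLE) || any(T > .T_MELT_ATM)) {
    stop("temperature outside the liquidus domain [251.15, 273.2] K ",
         "(below the ice-Ih/ice-III triple point or above the atmospheric ",
         "melting point)", call. = FALSE)
  }
  vapply(T, function(Ti) {
    if (Ti == .T_MELT_ATM) return(0)
    stats::uniroot(function(P) melting_temperature(P) - Ti,
                   interval = c(0, 2.1e8), tol = 1e-4)$root
  }, numeric(1))
}

#' Melting-point suppression and adjusted temperature
#'
#' The thermal-property fits for water and ice are referenced to atmospheric
#' pressure; at elevated pressure the model assumes the same temperature
#' dependence shifted by the melting-point suppression
#' \eqn{T_{sup}(P) = T_m(P) - T_m(0)}. `adjusted_temperature` returns
#' \eqn{T_{adj} = T - T_{sup}(P)}, the temperature at which the atmospheric
#' fits are evaluated.
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @return Adjusted temperature in K.
#' @export
adjusted_temperature <- function(T, P_gauge = 0) {
  T - (melting_temperature(P_gauge) - .liq_c0)
}

#' Logistic liquid phase fraction
#'
#' Liquid fraction across the pseudo phase-transition band,
#' \eqn{f(T,P) = 1 / (1 + e^{-a_0 (T - T_m(P))})}. With the default steepness
#' `a0 = 9.19` 1/K, `f` is 0.01 and 0.99 at half a transition width
#' (0.5 K) below and above the melting temperature, so 98 % of the transition
#' completes within \eqn{T_m \pm 0.5\Delta T_m} and it is practically complete
#' within \eqn{T_m \pm \Delta T_m} for \eqn{\Delta T_m = 1} K.
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @param a0 Logistic steepness in 1/K (default 9.19, matched to a 1 K
#'   transition width).
#' @return Liquid fraction in \[0, 1\]: 0 is fully solid, 1 fully liquid.
#' @export
#' @examples
#' phase_fraction(273.2, 0)        # 0.5 at the melting point
#' phase_fraction(273.2 - 0.5, 0)  # about 0.01
phase_fraction <- function(T, P_gauge = 0, a0 = 9.19) {
  stats::plogis(a0 * (T - melting_temperature(P_gauge)))
}

#' Temperature derivative of the liquid phase fraction
#'
#' Analytic logistic derivative \eqn{df/dT = a_0 f (1-f)}, peaking at
#' \eqn{a_0/4} at the melting temperature. This is the phase-transition-rate
#' factor multiplying the latent heat in the apparent specific heat.
#'
#' @inheritParams phase_fraction
#' @return Derivative in 1/K.
#' @export
phase_fraction_deriv <- function(T, P_gauge = 0, a0 = 9.19) {
  f <- phase_fraction(T, P_gauge, a0)
  a0 * f * (1 - f)
}

#' Latent-heat model
#'
#' Builds the specific-enthalpy-of-fusion model used by the apparent specific
#' heat. Two modes are supported:
#' \describe{
#'   \item{`"table"`}{(default) linear interpolation of a caller-supplied
#'     monotone `(Tm, L)` table in J/kg. The default table is anchored at the
#'     atmospheric fusion enthalpy of water (333.6 kJ/kg at 273.15 K) and at
#'     240 kJ/kg near the ice-Ih/ice-III triple point (251.15 K), the
#'     handbook value of the fusion enthalpy at the low end of the ice-Ih
#'     melting line.}
#'   \item{`"as_printed"`}{the quartic fit
#'     \eqn{1.617\times10^{-4}T_m^4 - 1.711\times10^{-1}T_m^3 + 67.94 T_m^2 -
#'     1.198\times10^4 T_m + 7.926\times10^5} evaluated exactly as published.
#'     Its four-significant-digit coefficients cancel catastrophically (terms
#'     of order 5e6 collapse to about 2.5e3) and its nominal kJ/kg scale does
#'     not match the fusion-enthalpy magnitude, so this mode is retained for
#'     audit only; transient simulations should use the table mode.}
#' }
#'
#' @param mode `"table"` or `"as_printed"`.
#' @param table Two-column matrix or data.frame `(Tm_K, L_J_per_kg)` for table
#'   mode; ignored otherwise.
#' @return An object of class `latent_model`.
#' @export
latent_model <- function(mode = c("table", "as_printed"), table = NULL) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(table)) table <- default_latent_table()
    table <- as.matrix(table)
    if (ncol(table) != 2 || nrow(table) < 2)
      stop("latent-heat table must have two columns (Tm K, L J/kg) and at ",
           "least two rows", call. = FALSE)
    table <- table[order(table[, 1]), , drop = FALSE]
  }
  structure(list(mode = mode, table = table), class = "latent_model")
}

#' @rdname latent_model
#' @export
default_latent_table <- function() {
  cbind(Tm_K = c(251.15, 273.15), L_J_per_kg = c(240e3, 333.6e3))
}

#' Specific enthalpy of fusion at a melting temperature
#'
#' @param Tm Melting temperature in K, in \[251.15, 273.2\].
#' @param model A [latent_model()]; the default is the anchored table mode.
#' @return Latent heat in J/kg (table mode) or the raw printed-fit value
#'   (`as_printed` mode).
#' @export
latent_heat <- function(Tm, model = latent_model()) {
  if (any(!is.finite(Tm)) || any(Tm < .T_TRIPLE) || any(Tm > .T_MELT_ATM)) {
    stop("melting temperature outside [251.15, 273.2] K", call. = FALSE)
  }
  if (!inherits(model, "latent_model"))
    stop("`model` must be a latent_model object", call. = FALSE)
  if (model$mode == "as_printed") {
    return((((1.617e-4 * Tm - 1.711e-1) * Tm + 67.94) * Tm - 1.198e4) * Tm +
             7.926e5)
  }
  if (is.null(model$table))
    stop("table mode requires a (Tm, L) table", call. = FALSE)
  stats::approx(model$table[, 1], model$table[, 2], xout = Tm, rule = 2)$y
}
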
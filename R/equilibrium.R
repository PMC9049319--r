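# Closed-form steady-state predictor: equilibrium pressure and phase split of
# a sealed chamber held at a given temperature.

#' Equilibrium state of an isochoric chamber at a hold temperature
#'
#' Determines the steady state of a sealed, rigid chamber of overall density
#' `rho_chamber` held at `T_hold`. If an all-liquid pressure solving
#' \eqn{\rho_l(T, P) = \rho_{chamber}} exists above the liquidus (that is,
#' with \eqn{T > T_m(P)}), the chamber stays liquid at that pressure.
#' Otherwise the state is two-phase: the pressure sits on the liquidus,
#' \eqn{P = P_{liq}(T)}, and the ice mass fraction follows the
#' specific-volume lever rule. Liquid-branch pressures are floored at
#' -101.325 kPa gauge (absolute vacuum; the model has no cavitation physics)
#' and flagged. Supercooling is never modeled: the predictor crystallizes on
#' the liquidus.
#'
#' @param T_hold Hold temperature in K, in \[251.15, 320\].
#' @param rho_chamber Sealed mass over cavity volume in kg/m^3; default is
#'   liquid water sealed at 0 C and atmospheric pressure.
#' @param eos Optional [water_eos()] used for density evaluation; default
#'   direct integration.
#' @return An `equilibrium_result` list: `T_hold_K`, `P_Pa`,
#'   `ice_mass_fraction`, `branch` (`"subcooled-liquid"` or `"two-phase"`),
#'   `clamped`.
#' @export
#' @examples
#' eq <- equilibrium_state(263.15)   # -10 C hold
#' eq$P_Pa / 1e6                     # about 111 MPa
#' eq$ice_mass_fraction              # about 0.38
equilibrium_state <- function(T_hold, rho_chamber = NULL, eos = NULL) {
  if (!is.finite(T_hold) || T_hold < .T_TRIPLE || T_hold > 320)
    stop("hold temperature outside [251.15, 320] K (below the ice-Ih / ",
         "ice-III triple point or above the model range)", call. = FALSE)
  if (is.null(rho_chamber)) rho_chamber <- water_density(273.15, 0, "liquid")
  rho_l_at <- function(P) {
    if (is.null(eos)) water_density(T_hold, P, "liquid")
    else eos_density(eos, T_hold, P, "liquid")
  }
  res <- function(P, F, branch, clamped = FALSE) {
    structure(list(T_hold_K = T_hold, P_Pa = P, ice_mass_fraction = F,
                   branch = branch, clamped = clamped),
              class = "equilibrium_result")
  }
  g <- function(P) rho_l_at(P) - rho_chamber
  lo <- .P_FLOOR + 1
  hi <- .P_MAX - 1e5
  if (g(lo) >= 0) {
    # liquid lighter than the chamber density even at the vacuum floor
    liquid_ok <- T_hold > melting_temperature(0)
    if (liquid_ok) return(res(.P_FLOOR, 0, "subcooled-liquid", clamped = TRUE))
  }
  P_l <- if (g(lo) < 0 && g(hi) > 0)
    stats::uniroot(g, c(lo, hi), tol = 1e-2)$root else NA_real_
  if (is.finite(P_l) &&
      T_hold > melting_temperature(max(min(P_l, .P_MAX), 0))) {
    return(res(P_l, 0, "subcooled-liquid"))
  }
  if (T_hold > .T_MELT_ATM)
    stop("no all-liquid state found above the atmospheric melting point; ",
         "chamber density outside the liquid range", call. = FALSE)
  P <- liquidus_pressure(T_hold)
  F <- ice_mass_fraction(T_hold, rho_chamber, eos)
  res(P, as.numeric(F), "two-phase")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "<equilibrium> %.2f C: %s, P = %.2f MPa, ice mass fraction = %.1f %%%s\n",
    x$T_hold_K - 273.15, x$branch, x$P_Pa / 1e6, 100 * x$ice_mass_fraction,
    if (x$clamped) " (clamped at vacuum floor)" else ""))
  invisible(x)
}

#' Stepwise equilibrium curve
#'
#' Evaluates [equilibrium_state()] over a vector of hold temperatures and
#' returns a table in reporting units.
#'
#' @param T_hold_K Hold temperatures in K.
#' @param rho_chamber Chamber density in kg/m^3 (default: sealed with liquid
#'   at 0 C, atmospheric).
#' @param eos Optional [water_eos()].
#' @return Data frame with columns `T_C`, `P_MPa`, `F_ice_percent`,
#'   `branch`.
#' @export
equilibrium_curve <- function(T_hold_K, rho_chamber = NULL, eos = NULL) {
  rows <- lapply(T_hold_K, equilibrium_state, rho_chamber = rho_chamber,
                 eos = eos)
  data.frame(
    T_C = vapply(rows, function(r) r$T_hold_K - 273.15, numeric(1)),
    P_MPa = vapply(rows, function(r) r$P_Pa / 1e6, numeric(1)),
    F_ice_percent = vapply(rows, function(r) 100 * r$ice_mass_fraction,
                           numeric(1)),
    branch = vapply(rows, function(r) r$branch, character(1))
  )
}
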
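# Equation of state for liquid water and ice Ih: thermal-expansion and
# compressibility fits integrated from printed reference states.
#
# Reference states (gauge pressure): liquid 958.3 kg/m^3 at (373.15 K, 0 Pa);
# ice 916.6 kg/m^3 at (273.15 K, 0 Pa). Density anywhere else follows from
#   rho(T, P) = rho_r * exp(-Int beta dT' + Int alpha dP')
# along a two-leg path. The canonical path holds the temperature at the
# reference value while integrating the compressibility from the reference to
# the target pressure, then holds the pressure at the target value while
# integrating the expansion coefficient to the target temperature. The
# "reversed" path swaps the leg order; because the liquid expansion fit
# depends on pressure while its compressibility fit does not, the two orders
# do not agree exactly (the fits are not thermodynamically closed) and the
# difference is bounded by a property test.

.RHO_REF_L <- 958.3    # kg/m^3 at (373.15 K, 0 Pa gauge), boiling point
.T_REF_L <- 373.15
.RHO_REF_S <- 916.6    # kg/m^3 at (273.15 K, 0 Pa gauge), freezing point
.T_REF_S <- 273.15
.P_FLOOR <- -101325    # gauge floor = absolute vacuum

.T_EOS_MIN <- 250
.T_EOS_MAX <- 373.15

#' Volumetric thermal expansion coefficient of liquid water
#'
#' Rational fit \eqn{\beta_l = (A + B/(C+D)) \times 10^{-4}} in 1/K, where A,
#' B, C are polynomials in temperature and D a cubic in pressure. The raw fit
#' evaluates to order unity; the 1e-4 output scale calibrates it to handbook
#' volumetric expansion values (2.07e-4 1/K at 20 C, a sign change at the 4 C
#' density maximum, negative values in the supercooled range at atmospheric
#' pressure).
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @return Volumetric expansion coefficient in 1/K.
#' @export
thermal_expansion_liquid <- function(T, P_gauge = 0) {
  A <- (8.498e-5 * T - 8.128e-2) * T + 4.785e1
  D <- ((-2.659e-23 * P_gauge + 3.289e-14) * P_gauge + 1.0e-5) * P_gauge
  B <- (5.563 * T - 3.763e3) * T + 5.560e5 + 5.596e-3 * T * D - 2.765e1 * D
  C <- ((-5.896e-4 * T + 3.658e-1) * T - 3.391e1) * T - 4.281e3
  den <- C + D
  if (any(abs(den) < 1e-8))
    stop("thermal_expansion_liquid: degenerate denominator C + D = 0",
         call. = FALSE)
  1e-4 * (A + B / den)
}

#' Volumetric thermal expansion coefficient of ice Ih
#'
#' Cubic fit in temperature; about 1.6e-4 1/K at 0 C, the volumetric value
#' for ice Ih (the fit is used directly in the density exponent, with no
#' factor-of-three linear-to-volumetric conversion).
#'
#' @param T Temperature in K.
#' @return Volumetric expansion coefficient in 1/K.
#' @export
thermal_expansion_ice <- function(T) {
  ((7.110e-10 * T - 5.561e-7) * T + 1.452e-4) * T - 1.250e-2
}

#' Isothermal compressibility of liquid water
#'
#' Quartic fit in gauge pressure, 4.417e-10 1/Pa at atmospheric pressure,
#' decreasing with pressure.
#'
#' @param P_gauge Gauge pressure in Pa.
#' @return Compressibility in 1/Pa.
#' @export
compressibility_liquid <- function(P_gauge) {
  (((8.860e-46 * P_gauge - 2.081e-36) * P_gauge + 1.998e-27) * P_gauge -
     1.092e-18) * P_gauge + 4.417e-10
}

#' Isothermal compressibility of ice Ih
#'
#' Reciprocal linear form with the parenthesized denominator in units of
#' 1e10 Pa: \eqn{\alpha_s = [10^{10}(5\times10^{-10}P - 1.199\times10^{-3}T +
#' 1.173)]^{-1}}, about 1.18e-10 1/Pa at (273.15 K, 0 Pa), matching handbook
#' ice-Ih compressibility.
#'
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @return Compressibility in 1/Pa.
#' @export
compressibility_ice <- function(T, P_gauge = 0) {
  den <- 1e10 * (5e-10 * P_gauge - 1.199e-3 * T + 1.173)
  if (any(den <= 0))
    stop("compressibility_ice: nonpositive denominator", call. = FALSE)
  1 / den
}

# Analytic pressure-leg integrals ------------------------------------------

# Int_0^P alpha_l dP' (quintic antiderivative of the quartic fit).
.int_alpha_l <- function(P) {
  ((((8.860e-46 / 5 * P - 2.081e-36 / 4) * P + 1.998e-27 / 3) * P -
      1.092e-18 / 2) * P + 4.417e-10) * P
}

# Int_0^P alpha_s(P', T) dP' at fixed temperature (log antiderivative).
.int_alpha_s <- function(T, P) {
  c0 <- 1e10 * (1.173 - 1.199e-3 * T)
  log1p(5 * P / c0) / 5
}

# Int_Tref^T beta_s dT' (quartic antiderivative of the cubic fit).
.int_beta_s <- function(T) {
  F <- function(x) (((7.110e-10 / 4 * x - 5.561e-7 / 3) * x + 1.452e-4 / 2) *
                      x - 1.250e-2) * x
  F(T) - F(.T_REF_S)
}

# 48-point Gauss-Legendre rule on [-1, 1] (Golub-Welsch), computed once.
.gl_rule <- local({
  n <- 48L
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
})

# Int_Tref_l^T beta_l(T', P) dT', Gauss-Legendre over the whole span.
# .int_beta_l_colP evaluates a whole temperature vector at one fixed
# pressure (used for table columns); .int_beta_l recycles pairwise.
.int_beta_l_colP <- function(T, P) {
  h <- (T - .T_REF_L) / 2
  m <- (T + .T_REF_L) / 2
  nodes <- outer(h, .gl_rule$x) + m
  h * as.numeric(thermal_expansion_liquid(nodes, P) %*% .gl_rule$w)
}
.int_beta_l <- function(T, P) {
  mapply(function(Ti, Pi) .int_beta_l_colP(Ti, Pi), T, P)
}

#' Density of liquid water, ice Ih, or their mixture
#'
#' Direct path-integrated density from the printed reference states: the
#' compressibility is integrated analytically along the pressure leg and the
#' expansion coefficient by Gauss-Legendre quadrature along the temperature
#' leg. `phase = "mixture"` blends the phases with the logistic fraction,
#' \eqn{\rho = f \rho_l + (1-f) \rho_s}.
#'
#' @param T Temperature in K, in \[250, 373.15\].
#' @param P_gauge Gauge pressure in Pa, in \[-101325, 2.12e8\] (the lower
#'   bound is the absolute-vacuum floor).
#' @param phase `"mixture"`, `"liquid"`, or `"ice"`.
#' @param path `"canonical"` (pressure leg at the reference temperature, then
#'   temperature leg at the target pressure) or `"reversed"` (leg order
#'   swapped); see the package vignette for the measured path-dependence of
#'   the fits.
#' @param a0 Logistic steepness for the mixture blend, 1/K.
#' @return Density in kg/m^3. Inputs are recycled to a common length.
#' @export
#' @examples
#' water_density(273.15, 0, "liquid")  # about 999.8 kg/m^3
#' water_density(273.15, 0, "ice")    # 916.6 kg/m^3 (reference state)
water_density <- function(T, P_gauge = 0,
                          phase = c("mixture", "liquid", "ice"),
                          path = c("canonical", "reversed"), a0 = 9.19) {
  phase <- match.arg(phase)
  path <- match.arg(path)
  n <- max(length(T), length(P_gauge))
  T <- rep_len(T, n)
  P <- rep_len(P_gauge, n)
  if (any(!is.finite(T)) || any(T < .T_EOS_MIN) || any(T > .T_EOS_MAX))
    stop("temperature outside the EOS domain [250, 373.15] K", call. = FALSE)
  if (any(!is.finite(P)) || any(P < .P_FLOOR) || any(P > .P_MAX))
    stop("gauge pressure outside the EOS domain [-101325, 2.12e8] Pa",
         call. = FALSE)
  rho_l <- function() {
    Pleg <- .int_alpha_l(P)
    Tleg <- if (path == "canonical") .int_beta_l(T, P) else .int_beta_l(T, 0)
    .RHO_REF_L * exp(Pleg - Tleg)
  }
  rho_s <- function() {
    Tat <- if (path == "canonical") .T_REF_S else T
    .RHO_REF_S * exp(.int_alpha_s(Tat, P) - .int_beta_s(T))
  }
  switch(phase,
    liquid = rho_l(),
    ice = rho_s(),
    mixture = {
      f <- phase_fraction(T, pmax(P, 0), a0)
      f * rho_l() + (1 - f) * rho_s()
    })
}

# Cached density table ------------------------------------------------------

#' Precompute a density lookup table
#'
#' Tabulates the log-density of each pure phase on a temperature-pressure
#' grid; queries interpolate each phase bilinearly in log-density and blend
#' with the exact logistic fraction, so the sharp transition band never has
#' to be resolved by the grid and on-grid probes reproduce the direct value
#' to quadrature round-off. Interpolation accuracy is verified on deterministic off-grid
#' probes at build time; a grid too coarse to meet the 0.1 % bound triggers a
#' warning carrying the measured maximum error.
#'
#' @param Tgrid Increasing temperature grid in K covering the run range
#'   (default 250 to 320.5 K in 0.5 K steps).
#' @param Pgrid Increasing gauge-pressure grid in Pa (default -101.325 kPa to
#'   212 MPa in 2 MPa steps).
#' @param a0 Logistic steepness for mixture queries, 1/K.
#' @param check_probes Number of off-grid verification probes.
#' @return An object of class `density_table` for [density_lookup()].
#' @export
build_density_table <- function(Tgrid = seq(250, 320.5, by = 0.5),
                                Pgrid = c(.P_FLOOR,
                                          seq(0, 212e6, by = 2e6)),
                                a0 = 9.19, check_probes = 100L) {
  Tgrid <- sort(unique(as.numeric(Tgrid)))
  Pgrid <- sort(unique(as.numeric(Pgrid)))
  if (length(Tgrid) < 4 || length(Pgrid) < 4)
    stop("density table grids need at least 4 points per axis", call. = FALSE)

  # Liquid: temperature-leg integral per pressure column (same
  # Gauss-Legendre rule as direct evaluation, so on-grid lookups reproduce
  # direct values to round-off), plus the analytic pressure leg.
  log_l <- matrix(NA_real_, length(Tgrid), length(Pgrid))
  for (j in seq_along(Pgrid)) {
    leg <- .int_beta_l_colP(Tgrid, Pgrid[j])
    log_l[, j] <- log(.RHO_REF_L) + .int_alpha_l(Pgrid[j]) - leg
  }
  log_s <- outer(-.int_beta_s(Tgrid), .int_alpha_s(.T_REF_S, Pgrid), "+") +
    log(.RHO_REF_S)

  tbl <- structure(list(Tgrid = Tgrid, Pgrid = Pgrid, log_l = log_l,
                        log_s = log_s, a0 = a0, max_rel_err = NA_real_),
                   class = "density_table")

  if (check_probes > 0) {
    # deterministic low-discrepancy probes (golden-ratio stride), off-grid
    i <- seq_len(check_probes)
    u <- (i * 0.6180339887498949) %% 1
    v <- (i * 0.7548776662466927) %% 1
    Tp <- min(Tgrid) + u * (max(Tgrid) - min(Tgrid))
    Pp <- pmax(0, min(Pgrid)) + v * (max(Pgrid) - pmax(0, min(Pgrid)))
    for (ph in c("liquid", "ice")) {
      direct <- water_density(Tp, Pp, ph)
      interp <- density_lookup(tbl, Tp, Pp, ph)
      err <- max(abs(interp / direct - 1))
      tbl$max_rel_err <- max(tbl$max_rel_err, err, na.rm = TRUE)
    }
    if (tbl$max_rel_err >= 1e-3)
      warning(sprintf(
        "density table grid too coarse: max interpolation error %.3g ",
        tbl$max_rel_err), call. = FALSE)
  }
  tbl
}

#' Interpolate a precomputed density table
#'
#' @param table A [build_density_table()] object.
#' @param T Temperature in K.
#' @param P_gauge Gauge pressure in Pa.
#' @param phase `"mixture"`, `"liquid"`, or `"ice"`.
#' @return Density in kg/m^3.
#' @export
density_lookup <- function(table, T, P_gauge,
                           phase = c("mixture", "liquid", "ice")) {
  phase <- match.arg(phase)
  n <- max(length(T), length(P_gauge))
  T <- rep_len(T, n)
  P <- rep_len(P_gauge, n)
  Tg <- table$Tgrid
  Pg <- table$Pgrid
  if (any(T < Tg[1]) || any(T > Tg[length(Tg)]) ||
      any(P < Pg[1]) || any(P > Pg[length(Pg)]))
    stop("density_lookup: query outside the tabulated grid", call. = FALSE)
  it <- pmin(pmax(findInterval(T, Tg), 1L), length(Tg) - 1L)
  ip <- pmin(pmax(findInterval(P, Pg), 1L), length(Pg) - 1L)
  wt <- (T - Tg[it]) / (Tg[it + 1L] - Tg[it])
  wp <- (P - Pg[ip]) / (Pg[ip + 1L] - Pg[ip])
  bil <- function(M) {
    v00 <- M[cbind(it, ip)]
    v10 <- M[cbind(it + 1L, ip)]
    v01 <- M[cbind(it, ip + 1L)]
    v11 <- M[cbind(it + 1L, ip + 1L)]
    (1 - wt) * (1 - wp) * v00 + wt * (1 - wp) * v10 +
      (1 - wt) * wp * v01 + wt * wp * v11
  }
  switch(phase,
    liquid = exp(bil(table$log_l)),
    ice = exp(bil(table$log_s)),
    mixture = {
      f <- phase_fraction(T, pmax(P, 0), table$a0)
      f * exp(bil(table$log_l)) + (1 - f) * exp(bil(table$log_s))
    })
}

#' Water equation-of-state configuration
#'
#' Bundles the reference states, the logistic steepness, the latent-heat
#' model, and (by default) a cached density table for fast repeated
#' evaluation inside the solvers.
#'
#' @param a0 Logistic steepness in 1/K.
#' @param latent A [latent_model()].
#' @param use_table Build and use a cached density table?
#' @param Tgrid,Pgrid Grids forwarded to [build_density_table()].
#' @return An object of class `water_eos`.
#' @export
water_eos <- function(a0 = 9.19, latent = latent_model(), use_table = TRUE,
                      Tgrid = seq(250, 320.5, by = 0.5),
                      Pgrid = c(.P_FLOOR, seq(0, 212e6, by = 2e6))) {
  tbl <- if (use_table) build_density_table(Tgrid, Pgrid, a0) else NULL
  structure(list(a0 = a0, latent = latent, table = tbl),
            class = "water_eos")
}

#' @rdname water_eos
#' @param eos A `water_eos` object.
#' @param T,P_gauge Query temperature (K) and gauge pressure (Pa).
#' @param phase `"mixture"`, `"liquid"`, or `"ice"`.
#' @export
eos_density <- function(eos, T, P_gauge, phase = "mixture") {
  if (!is.null(eos$table)) density_lookup(eos$table, T, P_gauge, phase)
  else water_density(T, P_gauge, phase, a0 = eos$a0)
}
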
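# Isochoric pressure response. Level 1: a single uniform gauge pressure
# closing mass conservation over the sealed chamber (the default coupling;
# pressure is nearly uniform whenever a connected liquid phase exists).
# Level 2: a 1D-radial Maxwell pseudo-viscoelastic stress solver for the
# infinite-cylinder benchmark geometry.

#' Wall model
#'
#' @param kind `"rigid"` (zero displacement on the water boundary) or
#'   `"elastic-annulus"` (plane-strain Lame thick cylinder of Type-316 steel,
#'   traction-free outer surface).
#' @param a,b Inner and outer wall radii in m (elastic-annulus only).
#' @param T_wall Wall temperature in K used to evaluate the steel modulus.
#' @return A `wall_model` object.
#' @export
wall_model <- function(kind = c("rigid", "elastic-annulus"), a = NULL,
                       b = NULL, T_wall = 273.15) {
  kind <- match.arg(kind)
  if (kind == "elastic-annulus") {
    if (is.null(a) || is.null(b) || !(b > a) || a <= 0)
      stop("elastic-annulus wall requires outer radius b > inner radius a > 0",
           call. = FALSE)
  }
  structure(list(kind = kind, a = a, b = b, T_wall = T_wall),
            class = "wall_model")
}

#' Lame thick-walled-cylinder radial displacement
#'
#' Plane-strain closed form for an elastic annulus under internal gauge
#' pressure `p` with a traction-free outer surface:
#' \eqn{u(r) = \frac{(1+\nu) p a^2}{E (b^2-a^2)}\left[(1-2\nu) r +
#' b^2/r\right]}.
#'
#' @param r Radius in m, `a <= r <= b`.
#' @param p Internal gauge pressure in Pa.
#' @param a,b Inner and outer radii in m.
#' @param E Elastic modulus in Pa.
#' @param nu Poisson ratio.
#' @return Radial displacement in m (positive outward).
#' @export
lame_radial_displacement <- function(r, p, a, b, E, nu) {
  A <- p * a^2 / (b^2 - a^2)
  (1 + nu) / E * ((1 - 2 * nu) * A * r + A * b^2 / r)
}

# Relative volumetric dilation of the water cavity from wall compliance.
.wall_dilation <- function(wall, P) {
  if (wall$kind == "rigid") return(rep_len(0, length(P)))
  E <- steel_property("elastic_modulus", wall$T_wall)
  nu <- steel_property("poisson", wall$T_wall)
  u_a <- lame_radial_displacement(wall$a, pmax(P, 0), wall$a, wall$b, E, nu)
  2 * u_a / wall$a
}

#' Level-1 uniform-pressure mass-conservation closure
#'
#' Finds the single gauge pressure at which the cell-summed mixture density
#' times cell volume equals the sealed water mass, by bracketed root finding
#' on \[-101.325 kPa, 212 MPa\]. With an elastic-annulus wall the cavity
#' volume is augmented by the plane-strain Lame dilation. If the mass balance
#' would require pressure below absolute vacuum the result is clamped at the
#' -101.325 kPa floor with a warning (the model contains no cavitation
#' physics).
#'
#' @param T_water Temperature of each water cell in K.
#' @param vol Volume of each water cell in m^3.
#' @param M0 Sealed water mass in kg.
#' @param eos A [water_eos()].
#' @param wall A [wall_model()].
#' @return Gauge pressure in Pa, with attribute `clamped` flagging a
#'   vacuum-floor clamp.
#' @export
solve_uniform_pressure <- function(T_water, vol, M0, eos,
                                   wall = wall_model("rigid")) {
  if (M0 <= 0) stop("sealed mass must be positive", call. = FALSE)
  mass_at <- function(P) {
    sum(eos_density(eos, T_water, P, "mixture") * vol) *
      (1 + .wall_dilation(wall, P)) - M0
  }
  lo <- .P_FLOOR + 1
  hi <- .P_MAX - 1e5
  m_lo <- mass_at(lo)
  if (m_lo >= 0) {
    warning("pressure clamped at the absolute-vacuum floor (-101.325 kPa); ",
            "the chamber is under tension it cannot sustain", call. = FALSE)
    return(structure(.P_FLOOR, clamped = TRUE))
  }
  if (mass_at(hi) < 0)
    stop("physical infeasibility: no pressure in [-101.3 kPa, 212 MPa] ",
         "closes the mass balance", call. = FALSE)
  P <- stats::uniroot(mass_at, c(lo, hi), tol = 1e-2)$root
  structure(P, clamped = FALSE)
}

#' Steady-state ice mass fraction by the specific-volume lever rule
#'
#' For a hold temperature on the ice-Ih liquidus, the equilibrium ice mass
#' fraction follows from the specific volumes of the pure phases at the
#' liquidus point and the overall chamber density:
#' \eqn{F_{ice} = (\rho_l^{-1} - \rho_{chamber}^{-1}) /
#' (\rho_l^{-1} - \rho_s^{-1})}, all densities evaluated at
#' \eqn{(T_{hold}, P_{liq}(T_{hold}))}.
#'
#' @param T_hold Hold temperature in K, in \[251.15, 273.2\].
#' @param rho_chamber Overall chamber density (sealed mass over cavity
#'   volume) in kg/m^3; default is liquid water sealed at 0 C, atmospheric.
#' @param eos A [water_eos()] or `NULL` for direct (non-tabulated)
#'   evaluation.
#' @return Ice mass fraction in \[0, 1\], with attribute `out_of_range` set
#'   when the unclipped lever value fell outside \[0, 1\].
#' @export
ice_mass_fraction <- function(T_hold, rho_chamber = NULL, eos = NULL) {
  if (is.null(rho_chamber)) rho_chamber <- water_density(273.15, 0, "liquid")
  P <- liquidus_pressure(T_hold)
  if (is.null(eos)) {
    rho_l <- water_density(T_hold, P, "liquid")
    rho_s <- water_density(T_hold, P, "ice")
  } else {
    rho_l <- eos_density(eos, T_hold, P, "liquid")
    rho_s <- eos_density(eos, T_hold, P, "ice")
  }
  F <- (1 / rho_l - 1 / rho_chamber) / (1 / rho_l - 1 / rho_s)
  out <- F < 0 | F > 1
  structure(pmin(pmax(F, 0), 1), out_of_range = any(out))
}

# --- Level-2: 1D-radial Maxwell pseudo-viscoelastic solver -----------------

#' Initialize a Level-2 radial mechanical state
#'
#' Staggered radial discretization of the water column of an infinitely long
#' cylinder: displacements live on nodes spanning \[0, a\], stresses and
#' temperatures on the cell midpoints between them. Stress components are
#' tension-positive (radial, hoop, axial); reported pressure is minus the
#' mean normal stress, so compression reads positive.
#'
#' @param r Increasing node radii in m, first node at 0, last at the water
#'   boundary.
#' @param rho0 Sealing density in kg/m^3 (the stress-free reference).
#' @param T0 Initial temperature in K (scalar or one value per cell).
#' @param P0 Initial uniform gauge pressure in Pa.
#' @return A `maxwell_state` object.
#' @export
maxwell_state <- function(r, rho0, T0, P0 = 0) {
  stopifnot(r[1] == 0, all(diff(r) > 0))
  n <- length(r)
  m <- n - 1L
  structure(list(r = r, r_c = (r[-1] + r[-n]) / 2, rho0 = rho0,
                 T = rep_len(T0, m),
                 srr = rep_len(-P0, m), stt = rep_len(-P0, m),
                 szz = rep_len(-P0, m),
                 u = numeric(n), P = rep_len(P0, m)),
            class = "maxwell_state")
}

#' Gauge pressure field from a Level-2 stress state
#'
#' Minus the mean of the three normal stresses at each stress cell
#' (compression-positive): a hydrostatic state \eqn{\sigma = -p I} reports
#' `p`, a pure shear state reports 0.
#'
#' @param state A [maxwell_state()].
#' @return Gauge pressure per stress cell in Pa.
#' @export
pressure_from_stress <- function(state) {
  -(state$srr + state$stt + state$szz) / 3
}

# Tangent bulk modulus of the mixture EOS, rho * (drho/dP)^-1, by centered
# finite difference on the density model.
.eos_bulk_modulus <- function(eos, T, P) {
  dP <- 2e5
  Pl <- pmax(P - dP, .P_FLOOR)
  Ph <- pmin(P + dP, .P_MAX)
  rho <- eos_density(eos, T, P, "mixture")
  drho <- (eos_density(eos, T, Ph, "mixture") -
             eos_density(eos, T, Pl, "mixture")) / (Ph - Pl)
  rho / pmax(drho, 1e-12)
}

# Invert the mixture EOS for pressure at a given density (vectorized
# bisection; mixture density is strictly increasing in P). Densities below
# the vacuum-floor value clamp to the floor, above the 212 MPa value to the
# ceiling.
.eos_pressure_of_density <- function(eos, T, rho_target, iters = 60L) {
  lo <- rep_len(.P_FLOOR + 1, length(rho_target))
  hi <- rep_len(.P_MAX - 1e5, length(rho_target))
  rho_lo <- eos_density(eos, T, lo, "mixture")
  rho_hi <- eos_density(eos, T, hi, "mixture")
  out_lo <- rho_target <= rho_lo
  out_hi <- rho_target >= rho_hi
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    too_low <- eos_density(eos, T, mid, "mixture") < rho_target
    lo <- ifelse(too_low, mid, lo)
    hi <- ifelse(too_low, hi, mid)
  }
  P <- (lo + hi) / 2
  P[out_lo] <- .P_FLOOR
  P[out_hi] <- .P_MAX - 1e5
  P
}

#' Advance the Level-2 Maxwell radial stress state one step
#'
#' Incremental update of the strain-rate decomposition on the infinite
#' cylinder (plane strain). Deviatoric stress relaxes through the
#' pseudo-viscosity \eqn{\eta(T,P)} with the exact single-step Maxwell
#' factor \eqn{1/(1 + G\Delta t/\eta)} (shear modulus G from E = 10 GPa,
#' nu = 0.33), so the liquid sheds shear stress in microseconds while ice is
#' effectively elastic. The mean normal stress is closed against the
#' equation of state: each stress cell carries the local density
#' \eqn{\rho_0/(1+e_v)} implied by its mechanical volumetric strain, and the
#' mean stress is minus the pressure at which the mixture EOS reproduces
#' that density at the current temperature. This local-EOS volumetric
#' closure folds thermal expansion, compressibility, and the phase-fraction
#' density jump into one driving term, is self-correcting (no incremental
#' drift), and reduces exactly to the Level-1 uniform-pressure
#' mass-conservation closure in uniform states (see the methods vignette
#' for why the nominal 10 GPa modulus is not used volumetrically). The
#' displacement increment solves quasi-static radial momentum balance,
#' \eqn{d(r\sigma_{rr})/dr = \sigma_{\theta\theta}}, on the staggered
#' grid by Newton iteration with the EOS tangent bulk modulus as the
#' Jacobian, under the wall condition: zero displacement for a rigid wall,
#' or plane-strain Lame compliance for an elastic steel annulus with a
#' traction-free outer surface.
#'
#' @param state A [maxwell_state()].
#' @param T_cells Temperature in K at the stress cells (scalar or
#'   per cell) at the new time level.
#' @param dt Time step in s, at most 2.5 s.
#' @param eos A [water_eos()].
#' @param wall A [wall_model()].
#' @param mech Water-domain elastic constants, see
#'   [water_mechanical_properties()].
#' @param tol Newton convergence tolerance on the cell pressures, Pa.
#' @param max_iter Maximum Newton iterations.
#' @return The updated `maxwell_state`.
#' @export
maxwell_step_radial <- function(state, T_cells, dt, eos,
                                wall = wall_model("rigid"),
                                mech = water_mechanical_properties(),
                                tol = 10, max_iter = 60L) {
  if (dt > 2.5 + 1e-12) stop("dt must not exceed 2.5 s", call. = FALSE)
  r <- state$r
  rc <- state$r_c
  n <- length(r)
  m <- n - 1L
  h <- diff(r)
  T_cells <- rep_len(T_cells, m)
  G <- mech$E / (2 * (1 + mech$nu))
  eta <- pseudo_viscosity(T_cells, pmax(pmin(state$P, .P_MAX), 0),
                          mech$eta_l, mech$eta_s, eos$a0)
  Df <- 1 + G * dt / eta
  mean_old <- (state$srr + state$stt + state$szz) / 3
  s_rr0 <- state$srr - mean_old
  s_tt0 <- state$stt - mean_old
  s_zz0 <- state$szz - mean_old
  strains <- function(u) {
    err <- diff(u) / h
    ett <- (u[-1] + u[-n]) / (2 * rc)
    list(err = err, ett = ett, ev = err + ett)
  }
  ev_old <- strains(state$u)$ev

  # cell stresses for a trial displacement increment du: deviatoric Maxwell
  # relaxation plus the local-EOS mean-stress closure
  stress_after <- function(du) {
    dn <- strains(du)
    srr_d <- (s_rr0 + 2 * G * (dn$err - dn$ev / 3)) / Df
    stt_d <- (s_tt0 + 2 * G * (dn$ett - dn$ev / 3)) / Df
    szz_d <- (s_zz0 + 2 * G * (-dn$ev / 3)) / Df
    rho_local <- state$rho0 / (1 + ev_old + dn$ev)
    P_cell <- .eos_pressure_of_density(eos, T_cells, rho_local)
    list(srr = srr_d - P_cell, stt = stt_d - P_cell, szz = szz_d - P_cell,
         P = P_cell)
  }
  wall_srr <- function(srr) {
    if (m == 1L) return(srr[m])
    srr[m] + (srr[m] - srr[m - 1L]) * (r[n] - rc[m]) / (rc[m] - rc[m - 1L])
  }
  resid_of <- function(s, du) {
    rs <- numeric(n)
    rs[1] <- du[1]                          # axis: u = 0 by symmetry
    i <- 2:m
    rs[i] <- (rc[i] * s$srr[i] - rc[i - 1L] * s$srr[i - 1L]) /
      (rc[i] - rc[i - 1L]) - (s$stt[i] + s$stt[i - 1L]) / 2
    if (wall$kind == "rigid") {
      rs[n] <- du[n]
    } else {
      E_w <- steel_property("elastic_modulus", wall$T_wall)
      nu_w <- steel_property("poisson", wall$T_wall)
      c_w <- lame_radial_displacement(wall$a, 1, wall$a, wall$b, E_w, nu_w)
      rs[n] <- du[n] + c_w * (wall_srr(s$srr) - wall_srr(state$srr))
    }
    rs
  }

  # approximate Jacobian: linearized constitutive with the EOS tangent bulk
  # modulus at the current state (frozen across Newton iterations)
  Kt <- .eos_bulk_modulus(eos, T_cells,
                          pmax(pmin(state$P, .P_MAX - 1e5), .P_FLOOR + 1))
  lin_resid <- function(du) {
    dn <- strains(du)
    srr <- (2 * G * (dn$err - dn$ev / 3)) / Df + Kt * dn$ev
    stt <- (2 * G * (dn$ett - dn$ev / 3)) / Df + Kt * dn$ev
    rs <- numeric(n)
    rs[1] <- du[1]
    i <- 2:m
    rs[i] <- (rc[i] * srr[i] - rc[i - 1L] * srr[i - 1L]) /
      (rc[i] - rc[i - 1L]) - (stt[i] + stt[i - 1L]) / 2
    if (wall$kind == "rigid") {
      rs[n] <- du[n]
    } else {
      E_w <- steel_property("elastic_modulus", wall$T_wall)
      nu_w <- steel_property("poisson", wall$T_wall)
      c_w <- lame_radial_displacement(wall$a, 1, wall$a, wall$b, E_w, nu_w)
      rs[n] <- du[n] + c_w * wall_srr(srr)
    }
    rs
  }
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- 1
    M[, k] <- lin_resid(e)
  }
  # row equilibration: boundary rows are O(1) while momentum rows carry
  # moduli over cell sizes, O(1e13)
  d <- pmax(apply(abs(M), 1, max), 1e-300)
  Mi <- solve(M / d)

  du <- numeric(n)
  s <- stress_after(du)
  P_prev <- s$P
  for (it in seq_len(max_iter)) {
    R <- resid_of(s, du)
    du <- du - as.numeric(Mi %*% (R / d))
    s <- stress_after(du)
    if (max(abs(s$P - P_prev)) < tol) break
    P_prev <- s$P
  }
  if (it == max_iter)
    stop("maxwell_step_radial: Newton iteration did not converge",
         call. = FALSE)
  state$srr <- s$srr
  state$stt <- s$stt
  state$szz <- s$szz
  state$u <- state$u + du
  state$T <- T_cells
  state$P <- s$P
  state
}
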
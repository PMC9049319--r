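test_that("Level-1 closure conserves mass and reproduces equilibrium holds", {
  eos <- test_eos()
  g <- build_grid(chamber_geometry("radial1d", 2.38e-3, 0.1778, 0), 12L)
  volw <- g$vol
  rho0 <- water_density(273.15, 0, "liquid")
  M0 <- rho0 * sum(volw)
  # all-liquid field at the sealing temperature is the mass reference: zero
  # pressure (sealed at +3 C, clear of the transition band)
  rho_seal <- water_density(276.15, 0, "liquid")
  P0 <- solve_uniform_pressure(rep(276.15, g$n), volw, rho_seal * sum(volw),
                               eos)
  expect_lt(abs(as.numeric(P0)), 1e3)
  # mass defect after each solve below 1e-8 relative
  for (Th in c(268.15, 263.15, 258.15, 253.15)) {
    P <- as.numeric(solve_uniform_pressure(rep(Th, g$n), volw, M0, eos))
    defect <- abs(sum(eos_density(eos, rep(Th, g$n), P, "mixture") * volw) -
                    M0) / M0
    expect_lt(defect, 1e-8)
    # two-phase uniform holds land near the liquidus (the logistic closure
    # offset is largest at the flattest part of the curve)
    expect_lt(abs(P - liquidus_pressure(Th)), 1.5e6)
  }
  # MS-1 steel annulus: pressure lower than rigid by less than 1 %
  P_rigid <- as.numeric(solve_uniform_pressure(rep(263.15, g$n), volw, M0,
                                               eos))
  P_ann <- as.numeric(solve_uniform_pressure(
    rep(263.15, g$n), volw, M0, eos,
    wall_model("elastic-annulus", a = 2.38e-3, b = 7.14e-3,
               T_wall = 263.15)))
  expect_lt(P_rigid - P_ann, 0.01 * P_rigid)
  expect_gt(P_rigid, P_ann)
  # vacuum-floor clamp is flagged, never silent
  expect_warning(
    Pc <- solve_uniform_pressure(rep(278, g$n), volw, 0.97 * M0, eos),
    "clamped")
  expect_true(attr(Pc, "clamped"))
  expect_error(solve_uniform_pressure(rep(251, g$n), volw, 1.2 * M0, eos),
               "infeasibility")
})

test_that("lever-rule ice fraction hits its endpoints and is monotone", {
  Th <- 263.15
  Pl <- liquidus_pressure(Th)
  rho_l <- water_density(Th, Pl, "liquid")
  rho_s <- water_density(Th, Pl, "ice")
  expect_equal(as.numeric(ice_mass_fraction(Th, rho_l)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(ice_mass_fraction(Th, rho_s)), 1, tolerance = 1e-9)
  # paper's scale-up value: 38.1 % at -10 C sealed at 0 C atmospheric
  expect_equal(100 * as.numeric(ice_mass_fraction(263.15)), 38.1,
               tolerance = 1.5 / 38.1)
  # monotone increasing as the hold temperature drops at fixed sealing
  Tg <- seq(273.1, 251.2, by = -0.5)
  F <- vapply(Tg, function(T) as.numeric(ice_mass_fraction(T)), numeric(1))
  expect_true(all(diff(F) > 0))
  expect_true(all(F >= 0 & F <= 1))
  expect_error(ice_mass_fraction(245), "domain")
  # out-of-range chamber density is clipped and flagged
  expect_true(attr(ice_mass_fraction(263.15, 900), "out_of_range"))
})

test_that("Lame closed form matches an independent elastic-annulus solution", {
  a <- 2.38e-3
  b <- 7.14e-3
  E <- steel_property("elastic_modulus", 263.15)
  nu <- 0.29
  p <- 111.2e6
  u_fd <- fd_annulus_displacement(p, a, b, E, nu)
  r <- seq(a, b, length.out = length(u_fd))
  u_cf <- lame_radial_displacement(r, p, a, b, E, nu)
  expect_lt(max(abs(u_fd - u_cf) / abs(u_cf)), 1e-3)
  expect_lt(abs(u_fd[1] - u_cf[1]) / u_cf[1], 1e-3)
})

test_that("pressure_from_stress is minus the mean normal stress", {
  st <- maxwell_state(seq(0, 1e-3, length.out = 5), 1000, 273.15, P0 = 0)
  st$srr <- rep(-5e6, 4)
  st$stt <- rep(-5e6, 4)
  st$szz <- rep(-5e6, 4)
  expect_equal(pressure_from_stress(st), rep(5e6, 4))   # hydrostatic
  st$srr <- rep(3e6, 4)
  st$stt <- rep(-3e6, 4)
  st$szz <- rep(0, 4)
  expect_equal(pressure_from_stress(st), rep(0, 4))     # traceless shear
})

test_that("Maxwell radial solver: no-op, Level-1 tracking, wall compliance", {
  eos <- test_eos()
  a <- 2.38e-3
  r <- seq(0, a, length.out = 21)
  rho0 <- water_density(273.15, 0, "liquid")

  # start from a self-consistent liquid state: isothermal steps change
  # nothing once the first step has equilibrated the state
  mx <- maxwell_state(r, rho0, T0 = 278.15, P0 = 0)
  mx <- maxwell_step_radial(mx, 278.15, 2.5, eos)
  ref <- mx
  mx <- maxwell_step_radial(mx, 278.15, 2.5, eos)
  expect_lt(max(abs(mx$srr - ref$srr)), 1)
  expect_lt(max(abs(mx$u - ref$u)), 1e-15)

  # uniform cooling into the two-phase region, rigid wall: mean pressure
  # tracks the Level-1 closure within 1 % (liquid relaxes deviatoric
  # stress on the eta_l/G microsecond timescale)
  mx <- maxwell_state(r, rho0, T0 = 273.15, P0 = 0)
  Tk <- 273.15
  for (k in 1:720) {   # 30 min at 2.5 s: ramp to -10 C at 0.5 C/min, hold
    Tk <- max(263.15, 273.15 - 0.5 * (k * 2.5 / 60))
    mx <- maxwell_step_radial(mx, Tk, 2.5, eos)
  }
  P1 <- as.numeric(solve_uniform_pressure(263.15, 1, rho0, eos))
  expect_equal(mean(mx$P), P1, tolerance = 0.01)
  expect_lt(diff(range(mx$P)), 0.01 * P1)

  # elastic MS-1 annulus: pressure within 1 % of rigid, outward wall motion
  wallm <- wall_model("elastic-annulus", a = a, b = 7.14e-3,
                      T_wall = 263.15)
  mw <- maxwell_state(r, rho0, T0 = 273.15, P0 = 0)
  Tk <- 273.15
  for (k in 1:720) {
    Tk <- max(263.15, 273.15 - 0.5 * (k * 2.5 / 60))
    mw <- maxwell_step_radial(mw, Tk, 2.5, eos, wall = wallm)
  }
  expect_lt(abs(mean(mw$P) - mean(mx$P)) / mean(mx$P), 0.01)
  expect_gt(mw$u[length(r)], 0)
  # wall displacement consistent with the Lame compliance at that pressure
  E_w <- steel_property("elastic_modulus", 263.15)
  u_lame <- lame_radial_displacement(a, mean(mw$P), a, 7.14e-3, E_w, 0.29)
  expect_equal(mw$u[length(r)], u_lame, tolerance = 0.02)
})
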
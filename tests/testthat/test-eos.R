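test_that("expansion and compressibility fits hit their anchor values", {
  # liquid volumetric expansion: handbook 2.07e-4 1/K at 20 C, near-zero at
  # the 4 C density maximum
  expect_equal(thermal_expansion_liquid(293.15, 0), 2.06e-4,
               tolerance = 0.01)
  expect_lt(abs(thermal_expansion_liquid(277.15, 0)), 2e-5)
  # ice volumetric expansion about 1.59e-4 1/K at 0 C
  expect_equal(thermal_expansion_ice(273.15), 1.59e-4, tolerance = 0.01)
  # compressibilities: printed constant term and the 1e10 Pa denominator
  expect_identical(compressibility_liquid(0), 4.417e-10)
  P <- 111.2e6
  direct <- 8.860e-46 * P^4 - 2.081e-36 * P^3 + 1.998e-27 * P^2 -
    1.092e-18 * P + 4.417e-10
  expect_equal(compressibility_liquid(P), direct, tolerance = 1e-14)
  expect_equal(compressibility_ice(273.15, 0), 1.18e-10, tolerance = 0.005)
  Pg <- seq(0, 210e6, length.out = 50)
  expect_true(all(compressibility_liquid(Pg) > 0))
  expect_true(all(compressibility_ice(260, Pg) > 0))
})

test_that("density integration recovers the reference states and 0 C liquid", {
  expect_equal(water_density(373.15, 0, "liquid"), 958.3, tolerance = 1e-9)
  expect_equal(water_density(273.15, 0, "ice"), 916.6, tolerance = 1e-9)
  # boiling-point reference integrated down to 0 C lands on liquid water
  rho0 <- water_density(273.15, 0, "liquid")
  expect_gt(rho0, 999)
  expect_lt(rho0, 1001)
  # independent quadrature oracle for the temperature leg at the -10 C
  # liquidus point (stats::integrate vs the Gauss-Legendre implementation)
  Pl <- liquidus_pressure(263.15)
  Tleg <- integrate(function(x) thermal_expansion_liquid(x, Pl), 373.15,
                    263.15, rel.tol = 1e-12)$value
  oracle <- 958.3 * exp(isofreeze:::.int_alpha_l(Pl) - Tleg)
  expect_equal(water_density(263.15, Pl, "liquid"), oracle,
               tolerance = 1e-10)
})

test_that("EOS densities are ordered and monotone in pressure", {
  Pg <- seq(0, 207e6, length.out = 30)
  for (T in c(255, 273.15, 300)) {
    expect_true(all(diff(water_density(T, Pg, "liquid")) > 0))
    expect_true(all(diff(water_density(T, Pg, "ice")) > 0))
  }
  # water denser than ice Ih everywhere on the liquidus
  Tl <- seq(251.2, 273.15, length.out = 40)
  Pl <- liquidus_pressure(Tl)
  expect_true(all(water_density(Tl, Pl, "liquid") >
                    water_density(Tl, Pl, "ice")))
  # mixture reduces to the pure phases away from the band
  expect_equal(water_density(280, 0, "mixture"),
               water_density(280, 0, "liquid"), tolerance = 1e-12)
  expect_equal(water_density(255, 0, "mixture"),
               water_density(255, 0, "ice"), tolerance = 1e-9)
  expect_error(water_density(200, 0), "EOS domain")
  expect_error(water_density(273, 3e8), "EOS domain")
})

test_that("leg-order reversal stays within the measured path-dependence bound", {
  # The printed fits are not thermodynamically closed: beta of the liquid
  # depends on pressure while alpha of the liquid does not. Measured over
  # the full domain the reversal changes ice densities by < 0.16 % and
  # liquid densities by up to ~2 % (at the cold high-pressure corner).
  Tg <- seq(250.5, 320, by = 2.5)
  dev_phase <- function(phase) {
    mx <- 0
    for (P in seq(0, 210e6, by = 15e6)) {
      a <- water_density(Tg, P, phase, path = "canonical")
      b <- water_density(Tg, P, phase, path = "reversed")
      mx <- max(mx, max(abs(b / a - 1)))
    }
    mx
  }
  expect_lt(dev_phase("ice"), 0.005)
  expect_lt(dev_phase("liquid"), 0.025)
})

test_that("cached density table reproduces direct integration", {
  eos <- test_eos()
  tbl <- eos$table
  expect_lt(tbl$max_rel_err, 1e-3)
  # on-grid probes are exact
  Ti <- tbl$Tgrid[c(5, 60, 100)]
  Pi <- tbl$Pgrid[c(2, 40, 90)]
  for (ph in c("liquid", "ice", "mixture")) {
    expect_equal(density_lookup(tbl, Ti, Pi, ph), water_density(Ti, Pi, ph),
                 tolerance = 1e-12, info = ph)
  }
  # deterministic off-grid probes within 0.1 %
  i <- seq_len(100)
  Tp <- 250 + ((i * 0.6180339887498949) %% 1) * 70
  Pp <- ((i * 0.7548776662466927) %% 1) * 210e6
  for (ph in c("liquid", "ice", "mixture")) {
    rel <- abs(density_lookup(tbl, Tp, Pp, ph) /
                 water_density(Tp, Pp, ph) - 1)
    expect_lt(max(rel), 1e-3)
  }
  # interpolated surface keeps pressure monotonicity along grid rows
  Pq <- seq(0, 210e6, length.out = 80)
  for (T in c(255.3, 273.3, 301.1)) {
    expect_true(all(diff(density_lookup(tbl, T, Pq, "liquid")) > 0))
    expect_true(all(diff(density_lookup(tbl, T, Pq, "ice")) > 0))
  }
  expect_error(density_lookup(tbl, 240, 0), "outside the tabulated grid")
  # a clearly too-coarse grid warns with the measured error
  expect_warning(build_density_table(seq(250, 320.5, by = 17),
                                     seq(0, 212e6, by = 5e7)),
                 "too coarse")
})
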
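# isofreeze

Coupled thermo-mechanical modeling of isochoric (constant-volume) freezing
of pure water, for cryobiology and biopreservation engineering.

When water freezes inside a sealed rigid chamber, the ~9 % volumetric
expansion of ice Ih is constrained and pressurizes the remaining liquid.
Higher pressure depresses the melting point, so the chamber rides down the
liquidus curve of the water phase diagram — from 0 °C at atmospheric
pressure to the liquid/ice-Ih/ice-III triple point near −22 °C and
207.4 MPa — and at any hold temperature only a bounded fraction of the water
turns to ice. This self-limiting behavior is the basis of isochoric
cryopreservation: material kept in the unfrozen core is stored cold without
ice damage. Designing such chambers requires knowing the pressure, the
temperature field, and the amount and location of ice over time — quantities
that are hard to measure behind thick sealed steel walls and that this
package computes.

## The model

* **Property stack** — the pressure-dependent melting temperature
  $T_m(P) = -5.701{\times}10^{-25}P^3 + 5.892{\times}10^{-18}P^2 -
  8.363{\times}10^{-8}P + 273.2\ \mathrm{K}$ and its inverse; a logistic
  liquid fraction $f = [1+e^{-a_0(T-T_m(P))}]^{-1}$ ($a_0 = 9.19$ K⁻¹,
  1 K transition width); conductivity and specific heat of each phase
  evaluated at the melting-point-suppression-adjusted temperature; an
  equation of state $\rho = \rho_r\exp(-\!\int\!\beta\,dT' +
  \!\int\!\alpha\,dP')$ integrated from printed reference states with
  published thermal-expansion and compressibility fits; Type-316 steel
  properties for the chamber wall.
* **Thermal solver** — implicit conservative finite-volume conduction on
  1D-radial or 2D-axisymmetric grids with the enthalpy (apparent heat
  capacity) method: the latent heat enters as $L(T_m)\,df/dT$, so freezing
  fronts never need to be traced. Convective (Robin) boundary driven by a
  surroundings-temperature schedule.
* **Mechanics** — Level 1: a uniform gauge pressure closing mass
  conservation over the sealed chamber (bracketed root find, mass defect
  < 10⁻⁸), with optional Lamé thick-cylinder wall compliance. Level 2: a
  1D-radial Maxwell pseudo-viscoelastic stress solver in which viscosity
  jumps from 10⁴ to 10¹⁴ Pa·s across the transition band, so liquid and ice
  are one continuum.
* **Equilibrium predictor** — closed-form steady state per hold
  temperature: liquidus pressure plus the specific-volume lever rule
  $F_{ice} = (\rho_l^{-1}-\rho_{ch}^{-1})/(\rho_l^{-1}-\rho_s^{-1})$.
* **Scenarios** — presets for the benchmark microreactor chamber
  (stepwise cooling to −20 °C), a wall-thickness study, and geometrically
  similar 3/150/500 ml idealized chambers, with a staggered coupled-run
  driver and CSV/JSON outputs.

See `vignettes/isochoric-freezing.Rmd` for the full account of the methods,
the unit and sign conventions adopted for the property fits, and known
limitations.

## Worked example

What happens when a rigid chamber sealed with liquid water at 0 °C is held
at −10 °C?

```r
library(isofreeze)

eq <- equilibrium_state(263.15)   # -10 C hold, default 0 C sealing
print(eq)
#> <equilibrium> -10.00 C: two-phase, P = 111.58 MPa, ice mass fraction = 38.3 %

equilibrium_curve(273.15 + c(-5, -10, -15, -20))
#>   T_C  P_MPa F_ice_percent    branch
#> 1  -5  59.22         24.07 two-phase
#> 2 -10 111.58         38.33 two-phase
#> 3 -15 155.86         47.59 two-phase
#> 4 -20 193.21         54.16 two-phase
```

The chamber equilibrates on the liquidus at 111.6 MPa with 38 % of the water
frozen — cold storage at −10 °C with most of the volume still liquid. The
pressures are the liquidus values at each hold; the fractions come from the
lever rule with both phase densities path-integrated to the liquidus point.

A full coupled transient of the 3 ml idealized chamber (sealed at +10 °C,
surroundings ramped at 0.4 °C/min to −10 °C and held, h = 900 W/m²K):

```r
run <- run_coupled(iso_preset("table1_3ml", max_time_s = 4800))
ts <- run$timeseries
response_time(ts$time_s, ts$T_centroid_K, 0.90, 283.15, 263.15)
#> [1] 58.29506   # minutes for the centroid to reach -8 C (90 % response)
tail(ts$P_Pa, 1) / 1e6
#> [1] 110.6886   # MPa, approaching the -10 C liquidus value
```

Early in this run the pressure dips to the vacuum floor (water contracts
between +10 and +4 °C; the driver logs the clamp), then climbs with ice
formation toward the liquidus. `write_run(run, "out/")` exports
`timeseries.csv` and `meta.json`; identical configurations reproduce
bitwise-identical files.

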
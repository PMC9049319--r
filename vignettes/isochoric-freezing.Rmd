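---
title: "Modeling isochoric freezing of water: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling isochoric freezing of water: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(isofreeze)
```

## The problem

Isochoric (constant-volume) cryopreservation stores biological material in a
sealed rigid chamber of water. As the chamber cools below 0 °C, some ice Ih
forms; because ice Ih is less dense than liquid water, the constrained
expansion pressurizes the remaining liquid, which in turn depresses the
melting point. The system therefore rides down the liquidus curve of the
water phase diagram — from 0 °C at atmospheric pressure to the
liquid/ice-Ih/ice-III triple point near −22 °C and 207.4 MPa — and at any
hold temperature only a bounded fraction of the water freezes. Material kept
in the unfrozen core is stored cold without ice damage.

`isofreeze` models this process as a coupled thermo-mechanical continuum
problem: transient conduction with phase change by the enthalpy (apparent
heat capacity) method, a pressure–temperature equation of state for liquid
water and ice Ih assembled from thermal-expansion and compressibility fits,
and an isochoric pressure closure — either a single uniform pressure from
mass conservation (Level 1) or a one-dimensional radial Maxwell
pseudo-viscoelastic stress solver (Level 2).

## The property stack

**Liquidus.** The melting temperature is a cubic in gauge pressure,
$T_m(P) = -5.701\times10^{-25}P^3 + 5.892\times10^{-18}P^2 -
8.363\times10^{-8}P + 273.2$ K, strictly decreasing to about −22.1 °C at
207.4 MPa. Its inverse `liquidus_pressure()` is obtained by bracketed root
finding; the round trip reproduces temperatures to better than $10^{-6}$ K.
The polynomial is evaluated for gauge pressures down to −101.325 kPa (the
absolute-vacuum floor used by the pressure closure), a 0.0085 K
extrapolation below its nominal lower end.

**Phase fraction.** The liquid fraction across the pseudo-transition band is
the logistic $f(T,P) = [1+e^{-a_0 (T - T_m(P))}]^{-1}$ with $a_0 = 9.19$
K$^{-1}$, matched to a transition width $\Delta T_m = 1$ K: $f$ is 0.01 and
0.99 at $T_m \mp 0.5$ K. The completion over $\pm 1$ K is exactly
$1 - 2/(1+e^{9.19}) = 0.99980$.

**Conductivity and specific heat.** Atmospheric-pressure fits for each pure
phase are evaluated at the adjusted temperature
$T_{adj} = T - [T_m(P) - T_m(0)]$, i.e. the temperature scale is shifted by
the melting-point suppression so one set of fits serves all pressures.
Mixture properties blend the phases with $f$; the apparent specific heat
adds the latent term $L(T_m)\,df/dT$, whose analytic logistic derivative
peaks at $a_0/4$ and integrates to $L(T_m)$ across the band, making the
method energy-conserving without front tracking.

**Latent heat.** The published quartic fit for $L(T_m)$ suffers catastrophic
cancellation at its four-significant-digit coefficients (terms of order
$5\times10^6$ collapse to $\sim2.5\times10^3$) and its nominal kJ/kg label
does not match the fusion-enthalpy scale, so it is kept only as an audit
mode (`latent_model("as_printed")`). The default is a monotone two-anchor
table, linear in $T_m$: 333.6 kJ/kg at 273.15 K (the atmospheric fusion
enthalpy) and 240 kJ/kg at 251.15 K (the handbook value near the
ice-Ih/ice-III triple point). Transient results are mildly sensitive to this
choice; equilibrium results are not.

**Equation of state.** Densities integrate
$\rho(T,P) = \rho_r \exp\left(-\int\beta\,dT' + \int\alpha\,dP'\right)$ from
the reference states 958.3 kg/m³ (liquid, 373.15 K, atmospheric) and
916.6 kg/m³ (ice, 273.15 K, atmospheric). Several conventions are fixed by
requiring the integration to reproduce known water densities:

* the exponent sign is $+\int\alpha - \int\beta$ (cooling from the boiling
  reference must *increase* liquid density — this recovers 1000.03 kg/m³ at
  0 °C from the 958.3 reference);
* the liquid expansion fit is scaled by $10^{-4}$ to K$^{-1}$ (it then
  matches the handbook volumetric value $2.07\times10^{-4}$ K$^{-1}$ at
  20 °C and changes sign at the 4 °C density maximum);
* both $\beta$ fits are used as *volumetric* coefficients (the ice fit
  evaluates to $1.6\times10^{-4}$ K$^{-1}$ at 0 °C, the volumetric value),
  with no factor-of-three conversion;
* the ice-compressibility denominator is read in units of $10^{10}$ Pa,
  giving $1.18\times10^{-10}$ Pa$^{-1}$ at 0 °C, the ice-Ih handbook value.

The canonical two-leg path holds temperature at the reference value while
integrating the compressibility to the target pressure, then holds pressure
while integrating the expansion coefficient to the target temperature. This
order matters: the liquid $\beta$ fit depends on pressure while the liquid
$\alpha$ fit does not, so the fits are not thermodynamically closed (they
violate the Maxwell relation $\partial\beta/\partial P =
-\partial\alpha/\partial T$). The canonical order is the one that reproduces
the published equilibrium ice fractions; reversing the legs changes ice
densities by at most 0.15 % but liquid densities by up to ~2 % at the cold
high-pressure corner of the domain (about 0.7 % at the −10 °C liquidus
point). The measured reversal bound is asserted by a property test at 2.5 %;
densities themselves are compared against independent quadrature oracles.

Pressure legs are integrated analytically (polynomial and logarithmic
antiderivatives); the liquid temperature leg uses a 48-point Gauss–Legendre
rule over the full span. For the solvers, `water_eos()` caches per-phase
log-density tables (0.5 K × 2 MPa grid) and blends them with the exact
logistic at query time, so the sharp transition band never has to be
resolved by the grid; off-grid interpolation error is verified below 0.1 %
at build time on deterministic low-discrepancy probes.

## Thermal solver

Conduction $\rho C_p \dot T = \nabla\cdot(k\nabla T)$ is discretized with a
conservative finite-volume scheme on a 1D-radial grid (infinite cylinder,
for the thick-walled benchmark chamber) or a 2D-axisymmetric grid (finite
cylinder, for the idealized scale-up chambers), with cell faces aligned
exactly on the water–steel interface and exact annulus cell volumes. The
outer surface carries a Robin condition $-k\,\partial T/\partial \hat n =
h(T_s - T_\infty)$ with a piecewise-linear surroundings schedule;
convection and radiation inside the chamber are neglected, as is natural
convection in the liquid.

Time stepping is implicit backward-Euler (step capped at 2.5 s) with Picard
iteration on the temperature-dependent coefficients. The latent term of the
apparent specific heat is evaluated as a *chord* of the logistic between
time levels, $L\,[f(T^{n+1}) - f(T^n)]/(T^{n+1} - T^n)$, rather than a point
derivative: this keeps the stiff latent peak energy-conserving even when a
cell traverses a sizeable part of the 1 K band in one step. The discrete
energy-balance residual (stored enthalpy change minus boundary flux) is
reported each step and sits at solver round-off, far below the 0.1 %
bound asserted in the tests; the constant-property limit of the scheme is
checked against the closed-form Bessel-series solution for Robin cooling of
an infinite cylinder.

Water properties in the thermal step are evaluated at the *previous* step's
pressure — the staggered coupling: thermal solve with $P^{n-1}$, then
mechanics with $T^n$, then boundary refresh.

## Mechanics

**Level 1 (default closure).** A single gauge pressure closes global mass
conservation: $\sum_i \rho_{mix}(T_i, P)\,V_i = M_0$, solved by bracketed
root finding to a relative mass defect below $10^{-8}$. With an elastic
steel wall the cavity volume is augmented by the plane-strain Lamé dilation
$2u(a)/a$; for the benchmark chamber this lowers the two-phase hold pressure
by under 0.1 %, supporting the rigid-wall idealization. Pressures below
absolute vacuum are clamped at −101.325 kPa with a logged warning (the model
contains no cavitation or evaporation physics; the published discussion
estimates the associated pressure deficit at 0.1 % of full scale).

**Level 2 (radial Maxwell solver).** On the infinite-cylinder benchmark
geometry, the total strain rate decomposes into creep, elastic, and
density-driven parts. Deviatoric stress relaxes through the pseudo-viscosity
$\eta(T,P) = f\eta_l + (1-f)\eta_s$ with $\eta_l = 10^4$ Pa s and
$\eta_s = 10^{14}$ Pa s, using the exact single-step Maxwell factor
$1/(1+G\Delta t/\eta)$ with $G$ from $E = 10$ GPa, $\nu = 0.33$: liquid
sheds shear stress in microseconds, ice is elastic on any practical time
scale, and the ten-order jump across the 1 K band welds the two into one
continuum. Displacements live on nodes, stresses on cell midpoints
(staggered, which avoids odd–even decoupling of the momentum operator
$d(r\sigma_{rr})/dr = \sigma_{\theta\theta}$); the wall condition is either
zero displacement or the Lamé compliance of the steel annulus with a
traction-free outer surface.

Two volumetric design choices deserve explanation:

* *Sign of the density-driven strain.* With tension-positive strains, the
  stress-free volumetric strain must be positive when the material would
  expand, i.e. $e_v = \rho_0/\rho - 1$; the form $(\rho-\rho_0)/\rho$ has
  the opposite sign and would drive compression on freezing expansion.
* *The volumetric modulus is the EOS tangent, not $E/[3(1-2\nu)]$.* The
  density already encodes the true compressibility of each phase. Using the
  nominal 10 GPa bulk modulus *and* a stress-free strain from the
  pressure-dependent density double-counts compression and would leave the
  rigid-chamber equilibrium about 19 % below the mass-conservation pressure
  in all-liquid states ($K\alpha_l \approx 4.3$) — contradicting the intent
  that the pseudo-viscoelastic device have no practical effect on stress
  development. Instead each stress cell carries the local density
  $\rho_0/(1+e_v)$ implied by its mechanical volumetric strain, and the mean
  normal stress is minus the pressure at which the mixture EOS reproduces
  that density at the current temperature. This local-EOS closure is
  self-correcting (no incremental drift) and reduces exactly to Level 1 in
  uniform states; 10 GPa remains the deviatoric stiffness. Incremental
  tangent-modulus integration was tried first and drifted by several percent
  through the transition band.

Reported pressure is minus the mean normal stress (compression positive), so
a hydrostatic state $\sigma = -p\,I$ reports $p$ and pure shear reports
zero. During transients the Level-2 pressure field is *not* uniform: any
cell with $f \lesssim 0.9999$ already has $\eta \gtrsim 10^{10}$ Pa s and
behaves quasi-elastically, so mid-transient spatial pressure spreads of a
few percent of full scale appear (the published 3 ml run reports 3.2 % of
full scale transiently); near hold ends the spread collapses and the
ring-averaged Level-2 pressure agrees with Level 1 to well under 2 %.

## Equilibrium predictor

`equilibrium_state()` gives the closed-form steady state: if a pressure
exists at which all-liquid water matches the chamber density *and* lies
above the liquidus, the chamber stays liquid (floored at the vacuum limit
and flagged when it cannot); otherwise the pressure sits on the liquidus and
the ice mass fraction follows the specific-volume lever rule
$F_{ice} = (\rho_l^{-1} - \rho_{ch}^{-1})/(\rho_l^{-1} - \rho_s^{-1})$,
with both densities at $(T_{hold}, P_{liq}(T_{hold}))$. Sealed with liquid
at 0 °C and atmospheric pressure, the predictor gives 24.1 / 38.3 / 47.6 /
54.2 % at −5 / −10 / −15 / −20 °C and 56.3 % at −22 °C. Supercooling is
never modeled: crystallization always happens on the liquidus.

A nuance of the logistic mixture: at a uniform two-phase hold the coupled
runs converge not exactly to the liquidus pressure but to the pressure at
which $f(T - T_m(P))$ equals the density lever fraction $f^*$ — an offset of
$\mathrm{logit}(f^*) / (a_0\,|dT_m/dP|)$. It is largest where the liquidus
is flattest: +2.1 % (+1.25 MPa) at −5 °C, +0.33 % at −10 °C, below 0.15 %
at −15/−20 °C. The published benchmark shows the same signature (its largest
deviation, 1.5 % or 0.92 MPa, is also at −5 °C). The same smearing means a
chamber sealed *at* 0 °C — 0.05 K below the fitted 273.2 K melting point —
equilibrates near 5 MPa rather than 0 before cooling starts.

## Scenarios and presets

`iso_preset()` ships the four study configurations: the MS-1 benchmark
(water radius 2.38 mm, steel wall 4.76 mm, sealed at 0 °C, surroundings
stepped to −20 °C in 5 °C holds with 1 °C/min ramps — the published ramp
rates were estimated, and the rate is exposed as a field — h = 900 W/m²K),
the wall-thickness study (0/1.19/2.38/4.76/9.52 mm at 20 °C/min,
h = 350 W/m²K), the Table-1 idealized cylinders (3/150/500 ml, 2.5:1 aspect,
+10 °C start, 0.4 °C/min ramp to −10 °C, h = 900 W/m²K), and the 1 vs
30 °C/min ramp study. The idealized chambers apply the convective condition
directly on the water surface (rigid massless wall) and are sealed at their
initial +10 °C — the only reading consistent with the published pressure dip
toward vacuum between +10 and +4 °C; an optional steel annulus is available.
The benchmark protocol seals at 0 °C after its equilibration step.

Runs are deterministic: identical configurations give bitwise-identical
outputs, and the run metadata echoes the full configuration.

## Problem sizes and numerical settings

Defaults were chosen once from convergence measurements: 16 cells across the
water radius (axial spacing twice the radial), dt = 2.5 s. For the 3 ml
chamber the 90 % centroid response time changes by 0.5 % when the radial
resolution is doubled to 32, so 16 (640 cells) is the documented
configuration; 8 cells is visibly under-resolved (+9 %). The benchmark
chamber uses 12 water cells plus the steel annulus. Picard iteration
converges in 2–4 sweeps away from the latent peak; the Level-2 Newton loop
uses the EOS tangent bulk modulus as a frozen preconditioner with row
equilibration of the assembled operator.

## What the model does and does not capture

The coupled 3 ml run reaches −8 °C at the centroid (90 % of the 20 °C full
scale) at 58.3 min against the published 55 min, and its hold pressure
settles within 0.5 % of the −10 °C liquidus value. The peak mid-height
radial temperature spread, measured between the centerline and the
wall-adjacent water cell (r/R = 0.97), is 1.36 °C at 50 min against a
published 0.97 °C; the near-wall profile is steep — the same run gives
0.43 °C at r/R = 0.8 and 0.86 °C at r/R = 0.9 — so this quantity depends
strongly on the (unstated) probe radius and on the latent-heat magnitude,
and should be read as scale agreement, not point agreement.

Out of scope, as in the source model: crystallization and nucleation
kinetics (no supercooling), evaporation and cavitation near vacuum, ice III
and anything below the −22 °C / 207.4 MPa triple point (runs stop with a
clear error if all liquid vanishes while cooling continues), CPA solutions,
temperature dependence of the water-domain elastic constants, and 3D
geometric detail such as the rounded corners of the idealized containers
(sharp-corner cylinders are used; the rounded corners existed to ease FEA
meshing of the mechanics problem). The wall-thickness and scale-up presets
reproduce the stated model, not the underlying experiments: the published
experimental transients additionally reflect transducer compliance and
3D effects that are explicitly not modeled here.
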
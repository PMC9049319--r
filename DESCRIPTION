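Package: isofreeze
Title: Coupled Thermo-Mechanical Modeling of Isochoric Freezing of Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the freezing of pure water inside a sealed, constant-volume
    (isochoric) chamber between atmospheric conditions and the liquid/ice-Ih/ice-III
    triple point (-22 C, 207.4 MPa). Provides the full temperature- and
    pressure-dependent property stack for liquid water, ice Ih and Type-316 steel
    (liquidus curve, latent heat, conductivity and specific heat with a logistic
    phase-fraction blend, thermal expansion and compressibility fits integrated
    into an equation of state), an enthalpy-method (apparent heat capacity)
    transient conduction solver on 1D-radial and 2D-axisymmetric finite-volume
    grids with convective boundaries, an isochoric pressure closure by mass
    conservation plus a 1D Maxwell pseudo-viscoelastic stress solver with rigid or
    compliant steel walls, closed-form equilibrium pressure and ice-fraction
    predictions on the liquidus, and scenario presets with a staggered coupled-run
    driver and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
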
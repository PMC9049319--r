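# Scenario configuration, study presets, and the staggered coupled-run
# driver: thermal step with the previous-step pressure, then the mechanics
# closure with the current temperatures, then boundary/property refresh.

#' Surroundings-temperature schedules
#'
#' `step_schedule` builds the stepwise cooling protocol used by the benchmark
#' chamber: starting at `T0_C`, ramp at `rate_C_per_min` to each target in
#' `steps_C` in turn and hold it for `hold_min` minutes.
#' `ramp_hold_schedule` ramps from `T0_C` to `T_end_C` at a constant rate and
#' holds thereafter.
#'
#' @param T0_C Initial surroundings temperature in C.
#' @param steps_C Vector of successive hold temperatures in C.
#' @param rate_C_per_min Ramp rate magnitude in C/min.
#' @param hold_min Hold duration at each step in minutes.
#' @return Data frame with columns `time_s`, `T_K`.
#' @export
step_schedule <- function(T0_C, steps_C, rate_C_per_min, hold_min) {
  t <- 0
  times <- 0
  temps <- T0_C
  cur <- T0_C
  for (Ts in steps_C) {
    t <- t + abs(Ts - cur) / rate_C_per_min * 60
    times <- c(times, t)
    temps <- c(temps, Ts)
    t <- t + hold_min * 60
    times <- c(times, t)
    temps <- c(temps, Ts)
    cur <- Ts
  }
  data.frame(time_s = times, T_K = temps + 273.15)
}

#' @rdname step_schedule
#' @param T_end_C Final surroundings temperature in C.
#' @export
ramp_hold_schedule <- function(T0_C, T_end_C, rate_C_per_min) {
  t_ramp <- abs(T_end_C - T0_C) / rate_C_per_min * 60
  data.frame(time_s = c(0, t_ramp), T_K = c(T0_C, T_end_C) + 273.15)
}

#' Scenario description for a coupled run
#'
#' @param geometry A [chamber_geometry()].
#' @param schedule Surroundings schedule data frame (`time_s`, `T_K`).
#' @param h Convective heat transfer coefficient in W/(m^2 K).
#' @param T0_K Initial (uniform) chamber temperature in K.
#' @param seal_T_K Sealing temperature in K: the chamber mass is the cavity
#'   volume times the liquid density at this temperature and atmospheric
#'   pressure.
#' @param dt Time step in s (at most 2.5 s).
#' @param resolution Cells across the water radius.
#' @param max_time_s Run duration in s.
#' @param mechanics_level 1 (uniform-pressure mass closure) or 2 (radial
#'   Maxwell solver; `radial1d` geometry only).
#' @param wall A [wall_model()] for the mechanics closure (the thermal wall
#'   is controlled by the geometry's `wall_thickness`).
#' @param latent A [latent_model()].
#' @param record_every Record every k-th step in the time series.
#' @param snapshot_every Record a Level-2 stress snapshot every k-th step
#'   (0 = none).
#' @return An `iso_scenario` object.
#' @export
iso_scenario <- function(geometry, schedule, h, T0_K, seal_T_K = T0_K,
                         dt = 2.5, resolution = 16L, max_time_s,
                         mechanics_level = 1L, wall = wall_model("rigid"),
                         latent = latent_model(), record_every = 1L,
                         snapshot_every = 0L) {
  if (dt > 2.5 + 1e-12)
    stop("dt must not exceed the 2.5 s cap", call. = FALSE)
  if (max_time_s > 0 && max(schedule$time_s) < 0)
    stop("schedule must be defined from time 0", call. = FALSE)
  if (mechanics_level == 2L && geometry$kind != "radial1d")
    stop("the Level-2 Maxwell solver supports radial1d geometry only",
         call. = FALSE)
  structure(list(geometry = geometry, schedule = schedule, h = h,
                 T0_K = T0_K, seal_T_K = seal_T_K, dt = dt,
                 resolution = as.integer(resolution),
                 max_time_s = max_time_s,
                 mechanics_level = as.integer(mechanics_level), wall = wall,
                 latent = latent, record_every = as.integer(record_every),
                 snapshot_every = as.integer(snapshot_every)),
            class = "iso_scenario")
}

#' Study presets
#'
#' Fully populated scenarios for the chambers and protocols studied with this
#' model:
#' \describe{
#'   \item{`benchmark_ms1`}{the MS-1 microreactor benchmark: 1D-radial water
#'     core of 2.38 mm radius inside a 4.76 mm Type-316 steel wall, sealed at
#'     0 C; surroundings stepped 0 to -20 C in 5 C holds (default 30 min)
#'     with 1 C/min ramps; h = 900 W/m^2 K; rigid mechanical wall.}
#'   \item{`wall_thickness_study`}{list of five MS-1 variants with wall
#'     thicknesses 0 (rigid massless), 1.19, 2.38, 4.76, 9.52 mm; 20 C/min
#'     ramps; h = 350 W/m^2 K.}
#'   \item{`table1_3ml`, `table1_150ml`, `table1_500ml`}{idealized
#'     axisymmetric cylinders (diameter x height 11.7 x 29.2, 43.1 x 107.7,
#'     63.5 x 158.7 mm), sealed at the initial +10 C; surroundings ramped at
#'     0.4 C/min to -10 C then held; h = 900 W/m^2 K; convective boundary
#'     directly on the water surface.}
#'   \item{`ramp_study`}{benchmark chamber at 1 vs 30 C/min ramp rates.}
#' }
#'
#' @param name Preset name.
#' @param hold_min Hold duration override for the stepwise protocols, min.
#' @param max_time_s Run-duration override, s.
#' @param resolution Radial-resolution override.
#' @return An `iso_scenario`, or a named list of them for the multi-variant
#'   presets.
#' @export
iso_preset <- function(name = c("benchmark_ms1", "wall_thickness_study",
                                "table1_3ml", "table1_150ml",
                                "table1_500ml", "ramp_study"),
                       hold_min = NULL, max_time_s = NULL,
                       resolution = NULL) {
  name <- match.arg(name)
  ms1_geom <- function(wall_mm = 4.76)
    chamber_geometry("radial1d", radius = 2.38e-3, height = 0.1778,
                     wall_thickness = wall_mm * 1e-3)
  ms1 <- function(rate, h, hold, wall_mm = 4.76, res = 12L) {
    sch <- step_schedule(0, c(-5, -10, -15, -20), rate, hold)
    iso_scenario(ms1_geom(wall_mm), sch, h = h, T0_K = 273.15,
                 seal_T_K = 273.15, dt = 2.5, resolution = res,
                 max_time_s = max(sch$time_s))
  }
  table1 <- function(d_mm, h_mm, tmax, res = 16L) {
    geom <- chamber_geometry("axisym2d", radius = d_mm / 2 * 1e-3,
                             height = h_mm * 1e-3, wall_thickness = 0)
    iso_scenario(geom, ramp_hold_schedule(10, -10, 0.4), h = 900,
                 T0_K = 283.15, seal_T_K = 283.15, dt = 2.5,
                 resolution = res, max_time_s = tmax)
  }
  sc <- switch(name,
    benchmark_ms1 = ms1(rate = 1, h = 900, hold = hold_min %||% 30),
    wall_thickness_study = {
      th <- c(0, 1.19, 2.38, 4.76, 9.52)
      out <- lapply(th, function(w)
        ms1(rate = 20, h = 350, hold = hold_min %||% 30, wall_mm = w))
      names(out) <- sprintf("wall_%.2fmm", th)
      out
    },
    table1_3ml = table1(11.7, 29.2, 9000),
    table1_150ml = table1(43.1, 107.7, 18000),
    table1_500ml = table1(63.5, 158.7, 18000),
    ramp_study = list(rate_1 = ms1(1, 900, hold_min %||% 30),
                      rate_30 = ms1(30, 900, hold_min %||% 30))
  )
  override <- function(s) {
    if (!is.null(max_time_s)) s$max_time_s <- max_time_s
    if (!is.null(resolution)) s$resolution <- as.integer(resolution)
    s
  }
  if (inherits(sc, "iso_scenario")) override(sc) else lapply(sc, override)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the staggered coupled thermo-mechanical simulation
#'
#' Advances the scenario with the staggered loop: each step solves the
#' thermal problem implicitly using the previous step's pressure, then the
#' mechanics closure (Level-1 uniform pressure, or the Level-2 radial
#' Maxwell solver) with the new temperatures, then refreshes the boundary
#' schedule. The run records probe temperatures at the chamber centroid and
#' the mid-height wall-adjacent water cell, the chamber gauge pressure, the
#' chamber ice mass fraction, the boundary heat flow, and the discrete
#' energy-balance residual.
#'
#' @param scenario An [iso_scenario()].
#' @param eos Optional prebuilt [water_eos()] (rebuilt from the scenario's
#'   latent model otherwise).
#' @param quiet Suppress progress messages?
#' @return An `iso_run` list: `timeseries` data frame, `meta` list,
#'   `final` state list, and optional `snapshots`.
#' @export
run_coupled <- function(scenario, eos = NULL, quiet = TRUE) {
  stopifnot(inherits(scenario, "iso_scenario"))
  grid <- build_grid(scenario$geometry, scenario$resolution)
  if (is.null(eos)) eos <- water_eos(latent = scenario$latent)
  bc <- convective_bc(scenario$h, scenario$schedule)
  w <- grid$water
  volw <- grid$vol[w]
  rho0 <- water_density(scenario$seal_T_K, 0, "liquid")
  M0 <- rho0 * sum(volw)
  T <- rep(scenario$T0_K, grid$n)
  mid_z <- scenario$geometry$height / 2
  p_centroid <- .probe_index(grid, 0, mid_z)
  p_edge <- .probe_index(grid, scenario$geometry$radius * 0.999, mid_z)
  wall_mech <- scenario$wall

  P <- as.numeric(solve_uniform_pressure(T[w], volw, M0, eos, wall_mech))
  mx <- NULL
  if (scenario$mechanics_level == 2L) {
    r_nodes <- grid$r_f[seq_len(grid$n_water_r + 1L)]
    mx <- maxwell_state(r_nodes, rho0, T0 = scenario$T0_K, P0 = P)
  }

  n_steps <- if (scenario$max_time_s <= 0) 0L
             else ceiling(scenario$max_time_s / scenario$dt)
  rec_idx <- if (n_steps == 0L) 0L
             else unique(c(seq(0L, n_steps, by = scenario$record_every),
                           n_steps))
  nrec <- length(rec_idx)
  ts <- matrix(NA_real_, nrec, 9,
               dimnames = list(NULL, c(
                 "time_s", "T_inf_K", "T_centroid_K", "T_edge_K", "P_Pa",
                 "ice_mass_fraction", "flux_W", "energy_residual_J",
                 "picard_iters")))
  snapshots <- list()
  clamp_events <- 0L
  rec <- function(row, t, st_flux, st_resid, st_it) {
    f <- phase_fraction(T[w], pmax(P, 0), eos$a0)
    ice <- sum((1 - f) * eos_density(eos, T[w], max(P, .P_FLOOR), "ice") *
                 volw) / M0
    ts[row, ] <<- c(t, ambient_temperature(bc, t), T[p_centroid], T[p_edge],
                    P, ice, st_flux, st_resid, st_it)
  }
  rec(1L, 0, 0, 0, 0)
  row <- 1L
  for (k in seq_len(n_steps)) {
    t_new <- k * scenario$dt
    st <- step_thermal(grid, T, P, bc, t_new, scenario$dt, eos)
    T <- st$T
    if (scenario$mechanics_level == 2L) {
      mx <- maxwell_step_radial(mx, T[seq_len(grid$n_water_r)],
                                scenario$dt, eos, wall_mech)
      # ring-volume-weighted mean water pressure drives the coupling
      P <- sum(mx$P * mx$r_c) / sum(mx$r_c)
    } else {
      Pn <- solve_uniform_pressure(T[w], volw, M0, eos, wall_mech)
      if (isTRUE(attr(Pn, "clamped"))) clamp_events <- clamp_events + 1L
      P <- as.numeric(Pn)
    }
    fmax <- max(phase_fraction(T[w], pmax(P, 0), eos$a0))
    if (fmax < 0.005 &&
        ambient_temperature(bc, t_new) < min(T[w]))
      stop(sprintf(paste0(
        "full solidification at step %d (t = %.1f min): all liquid has ",
        "vanished and the surroundings continue to cool; the sub-triple-",
        "point solid-state regime is outside this model"), k, t_new / 60),
        call. = FALSE)
    if (k %in% rec_idx) {
      row <- row + 1L
      rec(row, t_new, st$flux_W, st$energy_residual_J, st$iters)
    }
    if (scenario$snapshot_every > 0L && !is.null(mx) &&
        k %% scenario$snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        data.frame(time_s = t_new, r_m = mx$r_c, srr_Pa = mx$srr,
                   stt_Pa = mx$stt, szz_Pa = mx$szz,
                   u_m = (mx$u[-1] + mx$u[-length(mx$u)]) / 2, P_Pa = mx$P)
    }
    if (!quiet && k %% 200L == 0L)
      message(sprintf("t = %.1f min, T_centroid = %.2f C, P = %.2f MPa",
                      t_new / 60, T[p_centroid] - 273.15, P / 1e6))
  }
  meta <- list(
    package = "isofreeze",
    version = as.character(utils::packageVersion("isofreeze")),
    r_version = R.version.string,
    config = list(
      geometry = unclass(scenario$geometry),
      h_W_m2K = scenario$h, schedule = scenario$schedule,
      T0_K = scenario$T0_K, seal_T_K = scenario$seal_T_K,
      seal_density_kg_m3 = rho0, sealed_mass_kg = M0,
      dt_s = scenario$dt, resolution = scenario$resolution,
      max_time_s = scenario$max_time_s,
      mechanics_level = scenario$mechanics_level,
      wall = unclass(scenario$wall),
      latent_mode = scenario$latent$mode,
      latent_table = scenario$latent$table,
      record_every = scenario$record_every),
    diagnostics = list(
      steps = n_steps, clamp_events = clamp_events,
      max_picard_iters = if (nrec > 1) max(ts[-1, "picard_iters"]) else 0,
      cumulative_energy_residual_J = sum(abs(ts[-1, "energy_residual_J"]),
                                         na.rm = TRUE))
  )
  structure(list(timeseries = as.data.frame(ts), meta = meta,
                 final = list(T = T, P = P, maxwell = mx, grid = grid),
                 snapshots = if (length(snapshots)) snapshots else NULL),
            class = "iso_run")
}

#' @export
print.iso_run <- function(x, ...) {
  n <- nrow(x$timeseries)
  cat(sprintf(
    "<iso_run> %d records over %.1f min; final T_centroid = %.2f C, P = %.2f MPa, ice = %.1f %%\n",
    n, x$timeseries$time_s[n] / 60,
    x$timeseries$T_centroid_K[n] - 273.15, x$timeseries$P_Pa[n] / 1e6,
    100 * x$timeseries$ice_mass_fraction[n]))
  invisible(x)
}

#' Write a coupled run to disk
#'
#' Writes `timeseries.csv`, `meta.json`, and (for Level-2 runs with
#' snapshots) one CSV per stress snapshot under `snapshots/`. Identical
#' configurations produce bitwise-identical outputs.
#'
#' @param run An `iso_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$timeseries, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$snapshots)) {
    sd <- file.path(dir, "snapshots")
    dir.create(sd, showWarnings = FALSE)
    for (i in seq_along(run$snapshots)) {
      utils::write.csv(run$snapshots[[i]],
                       file.path(sd, sprintf("snapshot_%04d.csv", i)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
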
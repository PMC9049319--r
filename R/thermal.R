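# Transient conduction with the enthalpy (apparent heat capacity) method.
# Implicit backward-Euler finite-volume update with Picard iteration on the
# temperature-dependent properties; the latent-heat term is evaluated as a
# chord of the logistic fraction between time levels, which keeps the stiff
# apparent-Cp peak energy-conserving even when a cell traverses a sizeable
# part of the transition band in one step.

#' Convective boundary condition
#'
#' Robin condition on the chamber's outer surface: the boundary heat flux is
#' \eqn{-k \partial T/\partial n = h (T_s - T_\infty)} with a prescribed
#' heat transfer coefficient and a piecewise-linear surroundings temperature
#' schedule.
#'
#' @param h Heat transfer coefficient in W/(m^2 K), positive.
#' @param schedule Data frame or matrix with columns `time_s` and `T_K`
#'   defining the surroundings temperature by linear interpolation; constant
#'   extrapolation beyond the last breakpoint.
#' @return A `convective_bc` object.
#' @export
convective_bc <- function(h, schedule) {
  if (!is.finite(h) || h <= 0) stop("h must be positive", call. = FALSE)
  schedule <- as.matrix(schedule)
  if (ncol(schedule) != 2 || nrow(schedule) < 1 || any(!is.finite(schedule)))
    stop("schedule must be finite (time_s, T_K) breakpoints", call. = FALSE)
  structure(list(h = h, schedule = schedule), class = "convective_bc")
}

#' Surroundings temperature at a given time
#' @param bc A [convective_bc()].
#' @param t Time in s.
#' @return Temperature in K.
#' @export
ambient_temperature <- function(bc, t) {
  s <- bc$schedule
  if (nrow(s) == 1L) return(rep_len(s[1, 2], length(t)))
  stats::approx(s[, 1], s[, 2], xout = t, rule = 2)$y
}

# Evaluate per-cell conductivity and apparent volumetric heat capacity.
# T_it: current Picard iterate; T_old: previous time level (chord for latent).
.thermal_coeffs <- function(grid, T_it, T_old, P, eos) {
  w <- grid$water
  k <- numeric(grid$n)
  C <- numeric(grid$n)  # rho * cp_app, J/(m^3 K)
  Pw <- pmax(rep_len(P, grid$n)[w], 0)
  Tw <- T_it[w]
  k[w] <- mixture_conductivity(Tw, Pw, eos$a0)
  rho <- eos_density(eos, Tw, pmax(rep_len(P, grid$n)[w], .P_FLOOR), "mixture")
  cp <- mixture_specific_heat(Tw, Pw, eos$latent, eos$a0,
                              include_latent = FALSE)
  Tm <- melting_temperature(Pw)
  L <- latent_heat(Tm, eos$latent)
  dT <- Tw - T_old[w]
  f_new <- phase_fraction(Tw, Pw, eos$a0)
  lat <- ifelse(abs(dT) > 1e-9,
                (f_new - phase_fraction(T_old[w], Pw, eos$a0)) / dT,
                eos$a0 * f_new * (1 - f_new))
  C[w] <- rho * (cp + L * lat)
  if (any(!w)) {
    Ts <- T_it[!w]
    k[!w] <- steel_property("conductivity", Ts)
    C[!w] <- steel_property("density", Ts) *
      steel_property("specific_heat", Ts)
  }
  list(k = k, C = C)
}

# Assemble face conductances (W/K) from per-cell conductivity.
.face_conductance <- function(faces, k) {
  faces$area / (faces$d_o / k[faces$owner] + faces$d_n / k[faces$neigh])
}

#' Advance the temperature field one implicit step
#'
#' Backward-Euler conservative finite-volume update using the mixture
#' conductivity and apparent specific heat in water cells (evaluated at the
#' previous-step pressure, consistent with the staggered thermo-mechanical
#' coupling) and Type-316 steel properties in wall cells, with perfect
#' thermal contact at the water-steel interface and the convective condition
#' on the outer boundary. Properties are updated by Picard iteration until
#' the temperature iterate is stationary.
#'
#' @param grid An [build_grid()] grid.
#' @param T Temperature per cell in K at the current time level.
#' @param P_gauge Uniform gauge pressure (or per-water-cell vector) in Pa
#'   from the previous mechanics solve.
#' @param bc A [convective_bc()].
#' @param t_new Time at the end of the step, s (for the surroundings
#'   schedule).
#' @param dt Time step in s, at most 2.5 s.
#' @param eos A [water_eos()].
#' @param tol Picard convergence tolerance on the temperature iterate, K.
#' @param max_iter Maximum Picard iterations.
#' @return List with the new temperature field `T`, boundary heat flow into
#'   the domain `flux_W`, the discrete energy-balance residual
#'   `energy_residual_J`, and the iteration count `iters`.
#' @export
step_thermal <- function(grid, T, P_gauge, bc, t_new, dt, eos,
                         tol = 1e-7, max_iter = 50L) {
  if (dt > 2.5 + 1e-12)
    stop("time step exceeds the 2.5 s cap of the staggered coupling",
         call. = FALSE)
  n <- grid$n
  Tinf <- ambient_temperature(bc, t_new)
  T_it <- T
  use_sparse <- n > 200L
  rf <- grid$rfaces
  af <- grid$afaces
  bf <- grid$bfaces
  for (iter in seq_len(max_iter)) {
    co <- .thermal_coeffs(grid, T_it, T, P_gauge, eos)
    Grf <- .face_conductance(rf, co$k)
    Gaf <- if (!is.null(af)) .face_conductance(af, co$k) else numeric(0)
    Gb <- bf$area / (bf$d / co$k[bf$cell] + 1 / bc$h)
    Cdt <- co$C * grid$vol / dt
    diag_v <- Cdt
    add_at <- function(v, idx, val) {
      agg <- rowsum(val, idx)
      v[as.integer(rownames(agg))] <- v[as.integer(rownames(agg))] + agg[, 1]
      v
    }
    diag_v <- add_at(diag_v, rf$owner, Grf)
    diag_v <- add_at(diag_v, rf$neigh, Grf)
    if (length(Gaf)) {
      diag_v <- add_at(diag_v, af$owner, Gaf)
      diag_v <- add_at(diag_v, af$neigh, Gaf)
    }
    diag_v <- add_at(diag_v, bf$cell, Gb)
    b <- Cdt * T
    b <- add_at(b, bf$cell, Gb * Tinf)
    ii <- c(seq_len(n), rf$owner, rf$neigh)
    jj <- c(seq_len(n), rf$neigh, rf$owner)
    xx <- c(diag_v, -Grf, -Grf)
    if (length(Gaf)) {
      ii <- c(ii, af$owner, af$neigh)
      jj <- c(jj, af$neigh, af$owner)
      xx <- c(xx, -Gaf, -Gaf)
    }
    if (use_sparse) {
      A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
      T_new <- as.numeric(Matrix::solve(A, b))
    } else {
      A <- matrix(0, n, n)
      A[cbind(ii, jj)] <- 0
      for (kk in seq_along(ii)) A[ii[kk], jj[kk]] <- A[ii[kk], jj[kk]] + xx[kk]
      T_new <- as.numeric(solve(A, b))
    }
    delta <- max(abs(T_new - T_it))
    T_it <- T_new
    if (delta < tol) break
  }
  if (delta >= tol * 10)
    stop(sprintf(paste0("thermal step failed to converge in %d Picard ",
                        "iterations (residual %.3g K)"), max_iter, delta),
         call. = FALSE)
  if (any(T_it < 230) || any(T_it > 330))
    stop("solver divergence: temperature left the [230, 330] K range",
         call. = FALSE)
  flux <- sum(Gb * (Tinf - T_it[bf$cell]))
  resid <- sum(Cdt * (T_it - T)) - flux
  list(T = T_it, flux_W = flux, energy_residual_J = resid * dt, iters = iter)
}

#' Response time of the slowest interior probe
#'
#' Time, in minutes, at which a probe temperature first completes a fraction
#' `s` of the full-scale temperature change from the initial to the final
#' surroundings temperature, by linear interpolation of the recorded time
#' series.
#'
#' @param time_s Time vector in s.
#' @param T_probe Probe temperature in K at those times.
#' @param s Response fraction in \[0, 1\].
#' @param T_start,T_final Initial and final full-scale temperatures in K.
#' @return Time in minutes; `NA` with a warning if the fraction is never
#'   reached.
#' @export
response_time <- function(time_s, T_probe, s, T_start, T_final) {
  if (s < 0 || s > 1) stop("s must be in [0, 1]", call. = FALSE)
  if (s == 0) return(0)
  target <- T_start + s * (T_final - T_start)
  done <- if (T_final < T_start) T_probe <= target else T_probe >= target
  if (!any(done)) {
    warning(sprintf("response fraction %.2f never reached within the run", s),
            call. = FALSE)
    return(NA_real_)
  }
  k <- which(done)[1]
  if (k == 1L) return(time_s[1] / 60)
  t_cross <- time_s[k - 1L] + (target - T_probe[k - 1L]) *
    (time_s[k] - time_s[k - 1L]) / (T_probe[k] - T_probe[k - 1L])
  t_cross / 60
}
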
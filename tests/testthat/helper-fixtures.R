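# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# One EOS (with cached density table) per test session.
test_eos <- function() {
  if (is.null(.fixture_env$eos)) .fixture_env$eos <- water_eos()
  .fixture_env$eos
}

# Memoised coupled runs shared between tests (deterministic, so reuse is
# safe).
cached_run <- function(key, thunk) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- thunk()
  .fixture_env[[key]]
}

# Analytic transient conduction in an infinite cylinder with a Robin surface
# condition: theta(r, t)/theta0 as a Bessel series (independent closed-form
# oracle for the finite-volume solver).
bessel_cylinder_theta <- function(r_over_R, Fo, Bi, n_roots = 60) {
  f <- function(lam) lam * besselJ(lam, 1) - Bi * besselJ(lam, 0)
  roots <- numeric(n_roots)
  lo <- 1e-6
  k <- 0
  step <- 0.1
  while (k < n_roots) {
    hi <- lo + step
    if (f(lo) * f(hi) < 0) {
      k <- k + 1
      roots[k] <- uniroot(f, c(lo, hi), tol = 1e-12)$root
    }
    lo <- hi
  }
  sapply(r_over_R, function(x) {
    Cn <- (2 / roots) * besselJ(roots, 1) /
      (besselJ(roots, 0)^2 + besselJ(roots, 1)^2)
    sum(Cn * exp(-roots^2 * Fo) * besselJ(roots * x, 0))
  })
}

# Independent finite-difference solution of a plane-strain elastic annulus
# under internal pressure p (traction-free outer surface): returns radial
# displacement at the nodes. Oracle for the Lame closed form.
fd_annulus_displacement <- function(p, a, b, E, nu, n = 2000) {
  r <- seq(a, b, length.out = n)
  h <- r[2] - r[1]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  # sigma_rr = (lam + 2 mu) u' + lam u / r ; sigma_tt = lam u' + (lam+2mu) u/r
  # momentum: d(sigma_rr)/dr + (sigma_rr - sigma_tt)/r = 0
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  # inner boundary: sigma_rr(a) = -p  (one-sided derivative)
  A[1, 1] <- -(lam + 2 * mu) * 3 / (2 * h) + lam / r[1]
  A[1, 2] <- (lam + 2 * mu) * 4 / (2 * h)
  A[1, 3] <- -(lam + 2 * mu) / (2 * h)
  rhs[1] <- -p
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- (lam + 2 * mu) / h^2 - (lam + 2 * mu) / (2 * h * r[i])
    A[i, i] <- -2 * (lam + 2 * mu) / h^2 - (lam + 2 * mu) / r[i]^2
    A[i, i + 1] <- (lam + 2 * mu) / h^2 + (lam + 2 * mu) / (2 * h * r[i])
  }
  # outer boundary: sigma_rr(b) = 0
  A[n, n] <- (lam + 2 * mu) * 3 / (2 * h) + lam / r[n]
  A[n, n - 1] <- -(lam + 2 * mu) * 4 / (2 * h)
  A[n, n - 2] <- (lam + 2 * mu) / (2 * h)
  rhs[n] <- 0
  as.numeric(solve(A, rhs))
}
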
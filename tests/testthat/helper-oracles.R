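# Independent oracles used against the closed-form implementations.

# brute-force convolution of a one-sided exponential with a unit-area
# Gaussian: integral over the decay age u, adaptive quadrature
numeric_emg <- function(t, t0, sigma, tau) {
  vapply(t, function(ti) {
    stats::integrate(function(u) exp(-u / tau) * dnorm(ti - u, t0, sigma),
                     0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

# fourth-order ODE integration of the branching scheme driven by the
# Gaussian source (deSolve, RK4 on a fine grid), then interpolated
ode_populations <- function(params, t_out, dt = 0.1) {
  rhs <- function(t, y, p) {
    src <- p$f * dnorm(t, mean = p$t0, sd = p$sigma_irf)
    list(c(
      s2 = (1 - p$phi_hgs) * src - y[["s2"]] / p$tau_ic,
      s1 = y[["s2"]] / p$tau_ic - y[["s1"]] / p$tau_isc,
      tr = y[["s1"]] / p$tau_isc,
      hgs = p$phi_hgs * src
    ))
  }
  tmin <- min(c(t_out, params$t0 - 8 * params$sigma_irf))
  grid <- seq(tmin, max(t_out) + 2 * dt, by = dt)
  sol <- deSolve::rk4(c(s2 = 0, s1 = 0, tr = 0, hgs = 0), grid, rhs, params)
  interp <- function(col) approx(sol[, "time"], sol[, col], xout = t_out)$y
  tibble::tibble(
    t = t_out,
    p_s2 = interp("s2"), p_s1 = interp("s1"),
    p_t = interp("tr"), p_hgs = interp("hgs")
  )
}

# small, quick O 1s configuration for tests that loop
quick_config <- function(...) {
  cfg <- default_config("O1s")
  cfg$instrument$be_step <- 0.05
  cfg$instrument$delay_dense_step <- 50
  mods <- list(...)
  for (k in names(mods)) cfg[[k]] <- modifyList(cfg[[k]], mods[[k]])
  attr(cfg, "validated") <- NULL
  validate_config(cfg)
}
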
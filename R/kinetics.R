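#' Kinetic parameters of the branching relaxation scheme
#'
#' The model: a Gaussian excitation pulse promotes a fraction `f` of the
#' molecules; a branch `phi_hgs` returns instantaneously to the hot ground
#' state (HGS), the rest populates S2(pi pi*), which converts internally to
#' S1(n pi*) with time constant `tau_ic`; S1 crosses to the triplet manifold
#' with `tau_isc`. No S1 -> S0 recovery channel exists, so the ground-state
#' depletion never recovers.
#'
#' The instrument response is parameterized internally by its Gaussian sigma;
#' quoted cross-correlation widths (e.g. 80.5 fs) are treated as fwhm at the
#' interface, consistent with the quadrature sum of the 75 fs pump and 30 fs
#' probe durations.
#'
#' @param t0 Time zero (fs).
#' @param cc_fwhm Pump-probe cross-correlation fwhm (fs).
#' @param tau_ic S2 -> S1 internal-conversion time constant (fs, > 0).
#' @param tau_isc S1 -> triplet intersystem-crossing constant (fs, > 0).
#' @param phi_hgs Instantaneous hot-ground-state branching fraction, in
#'   \[0, 1\].
#' @param f Total excited fraction, in \[0, 1\].
#' @return A `trxps_kinetics` list with `sigma_irf` (fs) derived from
#'   `cc_fwhm`.
#' @export
#' @examples
#' kinetic_params(tau_ic = 17, tau_isc = 1600, cc_fwhm = 80.5,
#'                phi_hgs = 0.36, f = 0.09)
kinetic_params <- function(t0 = 0, cc_fwhm = 80.5, tau_ic = 17,
                           tau_isc = 1600, phi_hgs = 0.36, f = 0.09) {
  check_positive(cc_fwhm, "cc_fwhm")
  check_positive(tau_ic, "tau_ic")
  check_positive(tau_isc, "tau_isc")
  if (phi_hgs < 0 || phi_hgs > 1) {
    abort("`phi_hgs` must be in [0, 1].", class = "trxps_domain_error")
  }
  if (f < 0 || f > 1) {
    abort("`f` must be in [0, 1].", class = "trxps_domain_error")
  }
  structure(list(t0 = t0, sigma_irf = fwhm_to_sigma(cc_fwhm),
                 cc_fwhm = cc_fwhm, tau_ic = tau_ic, tau_isc = tau_isc,
                 phi_hgs = phi_hgs, f = f, irf_convention = "fwhm"),
            class = "trxps_kinetics")
}

#' Gaussian excitation profile
#'
#' Unit-area Gaussian excitation rate density and its cumulative fraction
#' (a smoothed step through the error function).
#'
#' @param t Delay grid (fs).
#' @param t0 Pulse centre (fs).
#' @param sigma Gaussian sigma (fs, > 0).
#' @return A tibble with columns `t`, `rate` (fs^-1), `cumulative`.
#' @export
excitation_profile <- function(t, t0 = 0, sigma) {
  check_positive(sigma, "sigma")
  tibble::tibble(
    t = t,
    rate = dnorm(t, mean = t0, sd = sigma),
    cumulative = pnorm(t, mean = t0, sd = sigma)
  )
}

#' Exponentially modified Gaussian
#'
#' Closed-form convolution of a unit-amplitude one-sided exponential decay
#' `exp(-(t - t0)/tau)` with a unit-area Gaussian of width `sigma`:
#' \deqn{h(t) = \tfrac12 e^{\sigma^2/2\tau^2 - (t-t_0)/\tau}
#'   \,\mathrm{erfc}\!\left(\frac{\sigma/\tau - (t-t_0)/\sigma}{\sqrt 2}\right).}
#' This is the elementary kinetic component under Gaussian excitation.
#' Evaluated through the scaled complementary error function
#' (`pracma::erfcx`) so that large `sigma/tau` ratios do not overflow.
#'
#' @param t Time(s), fs.
#' @param t0 Time zero (fs).
#' @param sigma Gaussian sigma (fs, > 0).
#' @param tau Exponential time constant (fs, > 0).
#' @return Values of the convolved decay (dimensionless, amplitude of the
#'   parent exponential).
#' @export
erfcx_safe <- function(x) {
  # pracma::erfcx loses to exp-overflow beyond ~26; use the asymptotic
  # expansion erfcx(x) ~ (1 - 1/2x^2 + 3/4x^4 - 15/8x^6) / (x sqrt(pi))
  # above 15, where it is accurate to < 1e-8 relative.
  out <- numeric(length(x))
  big <- x > 15
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 1 / (2 * xb^2) + 3 / (4 * xb^4) - 15 / (8 * xb^6)) /
      (xb * sqrt(pi))
  }
  out
}

emg <- function(t, t0, sigma, tau) {
  check_positive(sigma, "sigma")
  check_positive(tau, "tau")
  dt <- t - t0
  b <- (sigma / tau - dt / sigma) / sqrt(2)
  out <- numeric(length(dt))
  pos <- b >= 0
  # b >= 0: 0.5 exp(a) erfc(b) rewritten via erfcx avoids exp overflow
  out[pos] <- 0.5 * erfcx_safe(b[pos]) *
    exp(-dt[pos]^2 / (2 * sigma^2))
  # b < 0 (late times): erfc(b) in (1, 2) and the exponent is bounded
  a <- sigma^2 / (2 * tau^2) - dt[!pos] / tau
  out[!pos] <- 0.5 * pracma::erfc(b[!pos]) * exp(a)
  out
}

# convolution of (t/tau) exp(-t/tau) theta(t) with the Gaussian: the
# degenerate (tau_ic == tau_isc) sequential-filling branch, derived by
# differentiating the EMG with respect to the rate.
emg_degenerate <- function(t, t0, sigma, tau) {
  dt <- t - t0
  e <- emg(t, t0, sigma, tau)
  phi <- dnorm(dt / sigma) # standard normal density
  ((dt - sigma^2 / tau) * e + sigma * phi) / tau
}

#' State populations on a delay grid
#'
#' Closed-form populations of the branching scheme (see [kinetic_params()]):
#' \itemize{
#' \item `p_s2 = f (1-phi) EMG(tau_ic)`
#' \item `p_s1 = f (1-phi) tau_isc/(tau_isc - tau_ic) (EMG(tau_isc) -
#'   EMG(tau_ic))`, with the degenerate equal-constant limit handled
#'   analytically;
#' \item `p_t` is the remainder of the non-HGS branch;
#' \item `p_hgs = f phi C(t)` with `C` the cumulative excitation;
#' \item `p_depletion = -f C(t)`.
#' }
#' Populations conserve `p_s2 + p_s1 + p_t + p_hgs = f C(t)` identically.
#'
#' @param params A [kinetic_params()] object.
#' @param t Monotone delay grid (fs).
#' @return A tibble with columns `t`, `p_s2`, `p_s1`, `p_t`, `p_hgs`,
#'   `p_depletion`.
#' @export
populations <- function(params, t) {
  stopifnot(inherits(params, "trxps_kinetics"))
  if (is.unsorted(t)) {
    abort("`t` must be monotone increasing.", class = "trxps_domain_error")
  }
  with(params, {
    C <- pnorm(t, mean = t0, sd = sigma_irf)
    amp <- f * (1 - phi_hgs)
    e_ic <- emg(t, t0, sigma_irf, tau_ic)
    p_s2 <- amp * e_ic
    rel <- abs(tau_isc - tau_ic) / max(tau_ic, tau_isc)
    if (rel < 1e-9) {
      p_s1 <- amp * emg_degenerate(t, t0, sigma_irf, tau_ic)
    } else {
      e_isc <- emg(t, t0, sigma_irf, tau_isc)
      p_s1 <- amp * tau_isc / (tau_isc - tau_ic) * (e_isc - e_ic)
    }
    p_t <- pmax(amp * C - p_s2 - p_s1, 0)
    tibble::tibble(
      t = t, p_s2 = p_s2, p_s1 = p_s1, p_t = p_t,
      p_hgs = f * phi_hgs * C, p_depletion = -f * C
    )
  })
}
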
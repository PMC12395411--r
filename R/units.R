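#' Physical constants used throughout the package
#'
#' CODATA values, fixed to at least 8 significant digits. `speed_of_light`
#' is in cm/s (the natural unit for wavenumber conversions), `planck_hc` in
#' eV nm, and `boltzmann` in eV/K.
#'
#' @format A named list with elements `speed_of_light`, `planck_hc`,
#'   `boltzmann`.
#' @export
#' @examples
#' physical_constants$planck_hc
physical_constants <- list(
  speed_of_light = 2.99792458e10,   # cm / s (exact)
  planck_hc      = 1239.841984,     # eV nm
  boltzmann      = 8.617333262e-5   # eV / K
)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite."),
          class = "trxps_domain_error")
  }
  invisible(x)
}

#' Convert a vibrational wavenumber to an oscillation period
#'
#' A mode of wavenumber \eqn{\nu} (cm\eqn{^{-1}}) has period
#' \eqn{T = 10^{15} / (\nu c)} fs with \eqn{c} in cm/s. For uracil's
#' low-frequency skeletal modes this maps e.g. 292.7 cm\eqn{^{-1}} to a
#' 114 fs period.
#'
#' @param nu Wavenumber(s) in cm^-1; must be positive.
#' @return Period(s) in fs.
#' @export
#' @examples
#' wavenumber_to_period(114.6)  # ~291 fs
wavenumber_to_period <- function(nu) {
  check_positive(nu, "nu")
  1e15 / (nu * physical_constants$speed_of_light)
}

#' @rdname wavenumber_to_period
#' @param period Period(s) in fs; must be positive.
#' @export
period_to_wavenumber <- function(period) {
  check_positive(period, "period")
  1e15 / (period * physical_constants$speed_of_light)
}

#' Convert a wavelength to a photon energy
#'
#' \eqn{E = hc/\lambda} with \eqn{hc \approx 1239.84} eV nm; the 264 nm
#' pump used for uracil corresponds to 4.70 eV.
#'
#' @param lambda Wavelength(s) in nm; must be positive.
#' @return Photon energy in eV.
#' @export
wavelength_to_photon_energy <- function(lambda) {
  check_positive(lambda, "lambda")
  physical_constants$planck_hc / lambda
}

#' @rdname wavelength_to_photon_energy
#' @param energy Photon energy in eV; must be positive.
#' @export
photon_energy_to_wavelength <- function(energy) {
  check_positive(energy, "energy")
  physical_constants$planck_hc / energy
}

#' Convert between Gaussian fwhm and sigma
#'
#' fwhm = 2 sqrt(2 ln 2) sigma. Widths in this package are quoted as fwhm at
#' user-facing interfaces (matching how pulse durations and linewidths are
#' reported) and as sigma internally.
#'
#' @param fwhm,sigma Positive width(s).
#' @return The converted width, same units.
#' @export
fwhm_to_sigma <- function(fwhm) {
  check_positive(fwhm, "fwhm")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) {
  check_positive(sigma, "sigma")
  sigma * (2 * sqrt(2 * log(2)))
}

#' Equivalent vibrational temperature under equipartition
#'
#' Distributes a total internal energy over `n_modes` vibrational modes,
#' assigning k_B T per mode (kinetic plus potential energy). A 12-atom
#' molecule such as uracil has 3N - 6 = 30 modes, so one 4.70 eV UV photon
#' corresponds to roughly 1800 K.
#'
#' @param e_total Total vibrational energy in eV (>= 0).
#' @param n_modes Number of vibrational modes (default 30, uracil).
#' @return Temperature in K.
#' @export
#' @examples
#' equipartition_temperature(4.70)  # ~1.8e3 K
equipartition_temperature <- function(e_total, n_modes = 30) {
  if (!is.numeric(e_total) || any(e_total < 0)) {
    abort("`e_total` must be non-negative.", class = "trxps_domain_error")
  }
  if (!is.numeric(n_modes) || any(n_modes < 1)) {
    abort("`n_modes` must be at least 1.", class = "trxps_domain_error")
  }
  e_total / (n_modes * physical_constants$boltzmann)
}
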
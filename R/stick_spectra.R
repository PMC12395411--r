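#' Load the packaged core-level stick-spectrum tables
#'
#' Returns the theoretical O 1s or N 1s ionization energies of uracil in its
#' ground (GS), S1(n pi*) and S2(pi pi*) states, as computed at the
#' RASPT2/aug-cc-pVDZ level at the Franck-Condon geometry, together with the
#' ionized site and a free-text ionization character. Energies are
#' unshifted (theory scale); apply [apply_rigid_shift()] to align with
#' experiment (-2.4 eV for O 1s, -2.1 eV for N 1s).
#'
#' Pole strengths are not part of the published tables; the packaged default
#' is 1.0 per line (0.1 for the weak S2 shake-down satellite) and can be
#' overridden downstream.
#'
#' @param edge `"O1s"` or `"N1s"`.
#' @return A tibble with columns `edge`, `state`, `site`, `energy`
#'   (binding energy, eV), `strength`, `character`.
#' @export
#' @examples
#' load_stick_tables("O1s")
load_stick_tables <- function(edge = c("O1s", "N1s")) {
  edge <- tryCatch(match.arg(edge), error = function(e) {
    abort("`edge` must be \"O1s\" or \"N1s\".", class = "trxps_lookup_error")
  })
  path <- system.file("extdata", "stick_tables.tsv", package = "trxps",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab <- tab[tab$edge == edge, , drop = FALSE]
  tibble::tibble(
    edge = tab$edge, state = tab$state, site = tab$site,
    energy = tab$energy_eV, strength = tab$strength,
    character = tab$character
  )
}

#' Default triplet-state stick lines
#'
#' The published tables do not list triplet-state ionization energies; the
#' transient intensity in the 539-542 eV range (experimental scale) is
#' assigned to the 3-pipi* / 3-npi* states. These synthetic default lines
#' place that band inside region D and are configurable.
#'
#' @param edge `"O1s"` or `"N1s"`.
#' @return A tibble in the same shape as [load_stick_tables()], on the
#'   *experimental* energy scale (no further rigid shift required).
#' @export
default_triplet_sticks <- function(edge = c("O1s", "N1s")) {
  edge <- match.arg(edge)
  if (edge == "O1s") {
    tibble::tibble(
      edge = "O1s",
      state = c("T_pipi", "T_npi"),
      site = c("O8", "O8"),
      energy = c(540.6, 541.1),
      strength = c(1, 1),
      character = c("1s-1 3pipi* (synthetic default)",
                    "1s-1 3npi* (synthetic default)")
    )
  } else {
    tibble::tibble(
      edge = "N1s",
      state = c("T_pipi", "T_npi"),
      site = c("N3", "N3"),
      energy = c(406.9, 407.2),
      strength = c(1, 1),
      character = c("1s-1 3pipi* (synthetic default)",
                    "1s-1 3npi* (synthetic default)")
    )
  }
}

#' Rigidly shift a stick spectrum
#'
#' Adds a signed energy offset to every line, the standard alignment of
#' theoretical core-level energies with experiment (e.g. -2.4 eV for the
#' O 1s table, -2.1 eV for N 1s). Shifts compose additively.
#'
#' @param sticks A stick-spectrum tibble (see [load_stick_tables()]).
#' @param shift Signed shift in eV.
#' @return The shifted tibble.
#' @export
apply_rigid_shift <- function(sticks, shift) {
  stopifnot(is.numeric(shift), length(shift) == 1, is.finite(shift))
  dplyr::mutate(sticks, energy = .data$energy + shift)
}

#' Line-shape descriptor
#'
#' @param kind `"lorentzian"`, `"gaussian"` or `"voigt"`.
#' @param fwhm Full width at half maximum in eV (> 0). For `"voigt"` give
#'   `c(lorentzian, gaussian)` component fwhm values.
#' @return A `trxps_lineshape` list.
#' @export
lineshape <- function(kind = c("lorentzian", "gaussian", "voigt"), fwhm = 0.4) {
  kind <- match.arg(kind)
  n_need <- if (kind == "voigt") 2L else 1L
  if (!is.numeric(fwhm) || length(fwhm) != n_need || any(fwhm <= 0)) {
    abort("`fwhm` must be positive (length 2 for voigt).",
          class = "trxps_domain_error")
  }
  structure(list(kind = kind, fwhm = fwhm), class = "trxps_lineshape")
}

# unit-area profile of `shape` centred at 0, evaluated at de
lineshape_density <- function(de, shape) {
  switch(shape$kind,
    lorentzian = {
      g <- shape$fwhm / 2
      (g / pi) / (de^2 + g^2)
    },
    gaussian = dnorm(de, sd = fwhm_to_sigma(shape$fwhm)),
    voigt = {
      # numerical Gaussian smear of the Lorentzian on a fine quadrature
      sg <- fwhm_to_sigma(shape$fwhm[2])
      gl <- shape$fwhm[1] / 2
      u <- seq(-5 * sg, 5 * sg, length.out = 41)
      w <- dnorm(u, sd = sg)
      w <- w / sum(w)
      rowSums(outer(de, u, function(d, uu) (gl / pi) / ((d - uu)^2 + gl^2)) *
                rep(w, each = length(de)))
    }
  )
}

#' Broaden a stick spectrum onto an energy grid
#'
#' Sums a unit-area line profile (Lorentzian, Gaussian or Voigt) of the given
#' width over every stick, weighted by its strength; the numerically
#' integrated area then equals the total stick strength up to grid
#' truncation. A warning is issued when the grid does not cover every line
#' with at least a 5 fwhm margin.
#'
#' @param sticks Stick tibble with `energy` and `strength` columns.
#' @param shape A [lineshape()].
#' @param grid Strictly increasing energy grid (eV).
#' @param check_coverage Warn when the grid lacks a 5 fwhm margin around
#'   the lines (default `TRUE`); disable when evaluating tails on a
#'   sub-window on purpose.
#' @return A tibble with columns `energy`, `intensity`.
#' @export
broaden <- function(sticks, shape, grid, check_coverage = TRUE) {
  stopifnot(inherits(shape, "trxps_lineshape"))
  if (any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing.", class = "trxps_domain_error")
  }
  if (nrow(sticks) == 0) {
    return(tibble::tibble(energy = grid, intensity = rep(0, length(grid))))
  }
  margin <- 5 * max(shape$fwhm)
  if (check_coverage &&
      (min(sticks$energy) - min(grid) < margin ||
       max(grid) - max(sticks$energy) < margin)) {
    warning("energy grid does not cover all lines with a 5 fwhm margin",
            call. = FALSE)
  }
  intensity <- rep(0, length(grid))
  for (i in seq_len(nrow(sticks))) {
    intensity <- intensity +
      sticks$strength[i] * lineshape_density(grid - sticks$energy[i], shape)
  }
  tibble::tibble(energy = grid, intensity = intensity)
}

#' Skewed hot-ground-state line
#'
#' Molecules returned to the electronic ground state carry the full photon
#' energy as vibrational excitation; their core line appears slightly above
#' the cold ground-state energy, broadened (~1.6 eV fwhm) and asymmetric.
#' Modelled as a skew-normal profile with location `center`, scale
#' `width_sigma` and shape `asymmetry` (>= 0 skews toward high binding
#' energy), normalized to the given `area`.
#'
#' @param grid Energy grid (eV).
#' @param center Location parameter (eV), i.e. the cold GS energy plus the
#'   time-dependent drift.
#' @param width_sigma Scale parameter in eV (> 0).
#' @param asymmetry Skew-normal shape parameter (>= 0).
#' @param area Integrated area the line represents (population it carries).
#' @return A tibble with columns `energy`, `intensity`.
#' @export
hgs_spectrum <- function(grid, center, width_sigma = fwhm_to_sigma(1.6),
                         asymmetry = 0.8, area = 1) {
  check_positive(width_sigma, "width_sigma")
  if (asymmetry < 0) {
    abort("`asymmetry` must be >= 0.", class = "trxps_domain_error")
  }
  z <- (grid - center) / width_sigma
  dens <- 2 / width_sigma * dnorm(z) * pnorm(asymmetry * z)
  tibble::tibble(energy = grid, intensity = area * dens)
}

# skew-normal density values on arbitrary points (internal)
skew_normal_density <- function(x, center, sigma, alpha) {
  z <- (x - center) / sigma
  2 / sigma * dnorm(z) * pnorm(alpha * z)
}

#' Compose a population-weighted transient spectrum
#'
#' Builds the expected UV-on minus UV-off *difference* spectrum (or the full
#' UV-on spectrum) from per-state broadened spectra and state populations.
#' Every excited-state spectrum is normalized so that its total area equals
#' the area of the ground-state lines it replaces, which enforces the
#' experimental balance: the integrated depletion equals the integrated
#' excited-state signal.
#'
#' @param state_spectra Named list of broadened-spectrum tibbles (common
#'   grid), including `"GS"`.
#' @param populations Named numeric vector of state population fractions
#'   (excluding GS), e.g. `c(S1_npi = 0.05, T_pipi = 0.01)`.
#' @param f Total excited fraction; the sum of `populations` must not
#'   exceed it (within rounding).
#' @param include_depletion If `TRUE` (default) the GS contribution is
#'   scaled by minus the cumulative excited population, yielding a signed
#'   difference spectrum; if `FALSE` the positive excited sum alone.
#' @param gs_area Area of the depleted ground-state signal per molecule;
#'   defaults to the integral of the GS spectrum.
#' @return A tibble with columns `energy`, `intensity` (signed when
#'   depletion is included).
#' @export
composite_spectrum <- function(state_spectra, populations, f,
                               include_depletion = TRUE, gs_area = NULL) {
  grids <- purrr::map(state_spectra, "energy")
  g0 <- grids[[1]]
  same <- purrr::map_lgl(grids, ~ length(.x) == length(g0) &&
                           max(abs(.x - g0)) < 1e-9)
  if (!all(same)) {
    abort("state spectra are not on a common energy grid.",
          class = "trxps_alignment_error")
  }
  if (any(populations < 0)) {
    abort("populations must be non-negative.", class = "trxps_domain_error")
  }
  cum_exc <- sum(populations)
  if (cum_exc > f + 1e-9) {
    abort("sum of excited populations exceeds `f`.",
          class = "trxps_domain_error")
  }
  dx <- diff(g0)
  quad <- function(y) sum((y[-1] + y[-length(y)]) / 2 * dx)
  gs <- state_spectra[["GS"]]$intensity
  if (is.null(gs_area)) gs_area <- quad(gs)
  out <- rep(0, length(g0))
  for (s in names(populations)) {
    if (populations[[s]] == 0) next
    ys <- state_spectra[[s]]$intensity
    a <- quad(ys)
    if (a <= 0) next
    out <- out + populations[[s]] * ys * (gs_area / a)
  }
  if (include_depletion) out <- out - cum_exc * gs
  tibble::tibble(energy = g0, intensity = out)
}

#' Default energy grid for an edge
#'
#' O 1s: 528-550 eV; N 1s: 400-414 eV; step 0.02 eV. Covers all table lines
#' and the integration regions with margin.
#'
#' @param edge `"O1s"` or `"N1s"`.
#' @param step Grid step in eV.
#' @return Numeric vector of binding energies.
#' @export
default_energy_grid <- function(edge = c("O1s", "N1s"), step = 0.02) {
  edge <- match.arg(edge)
  if (edge == "O1s") seq(528, 550, by = step) else seq(400, 414, by = step)
}
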
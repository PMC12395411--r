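#' Simulate coherent bond-length series
#'
#' The pi -> pi* excitation suddenly extends the C4O8 and C5C6 double bonds
#' by ~0.1 A; the subsequent motion is modelled per coordinate as
#' \deqn{L_b(t) = L_{eq,b} + \sum_m \theta(t)\,A_m\,(1 - e^{-t/\tau_m}
#'   \cos(\omega_m t + \phi_m)),}
#' i.e. a step extension carrying a damped cosine. An auxiliary effective
#' ring coordinate (label `"ring"`) carries the low-frequency mode that
#' modulates the hot-ground-state line.
#'
#' @param modes List of mode descriptors: `freq_cm1`, `bond`
#'   (`"C4O8"`, `"C5C6"` or `"ring"`), `amp_A`, `damp_fs`, `phase`.
#' @param t Monotone delay grid (fs).
#' @param equilibrium Named equilibrium lengths (A).
#' @return A tibble with columns `t`, `bond`, `length`.
#' @export
simulate_bond_series <- function(modes, t,
                                 equilibrium = c(C4O8 = 1.22, C5C6 = 1.34,
                                                 ring = 1.40)) {
  if (is.unsorted(t)) {
    abort("`t` must be monotone increasing.", class = "trxps_domain_error")
  }
  bonds <- unique(purrr::map_chr(modes, "bond"))
  purrr::map(bonds, function(b) {
    dev <- rep(0, length(t))
    for (m in modes) {
      if (m$bond != b) next
      check_positive(m$freq_cm1, "freq_cm1")
      check_positive(m$damp_fs, "damp_fs")
      omega <- 2 * pi / wavenumber_to_period(m$freq_cm1)
      phase <- m$phase %||% 0
      dev <- dev + ifelse(
        t >= 0,
        m$amp_A * (1 - exp(-t / m$damp_fs) * cos(omega * t + phase)),
        0
      )
    }
    tibble::tibble(t = t, bond = b,
                   length = unname(equilibrium[[b]]) + dev)
  }) |>
    dplyr::bind_rows()
}

#' Apply vibrational modulation to stick-line energies
#'
#' Shifts coupled line energies linearly with the bond-length deviation
#' from equilibrium; strengths are unchanged (the ionization cross sections
#' are assumed constant).
#'
#' @param sticks Stick tibble (columns `state`, `energy`, `strength`, ...),
#'   whose `energy` column is interpreted at the *unmodulated* positions.
#' @param bonds Output of [simulate_bond_series()].
#' @param couplings List of entries `state`, `energy_eV` (the line's
#'   table energy, used as identifier), `bond`, `slope_eV_per_A`.
#' @param equilibrium Named equilibrium lengths (A), as in
#'   [simulate_bond_series()].
#' @return A tibble with columns `t`, plus the stick columns, `energy` now
#'   time dependent.
#' @export
modulated_sticks <- function(sticks, bonds, couplings,
                             equilibrium = c(C4O8 = 1.22, C5C6 = 1.34,
                                             ring = 1.40)) {
  tg <- unique(bonds$t)
  dev <- tidyr::pivot_wider(bonds, names_from = "bond",
                            values_from = "length")
  shift_of <- function(state, energy) {
    total <- rep(0, length(tg))
    for (cp in couplings) {
      if (cp$state == state && abs(cp$energy_eV - energy) < 1e-6) {
        if (!cp$bond %in% names(dev)) {
          abort(paste0("coupling references unknown bond series `",
                       cp$bond, "`."), class = "trxps_config_error")
        }
        total <- total + cp$slope_eV_per_A *
          (dev[[cp$bond]] - unname(equilibrium[[cp$bond]]))
      }
    }
    total
  }
  for (cp in couplings) {
    hit <- sticks$state == cp$state & abs(sticks$energy - cp$energy_eV) < 1e-6
    if (!any(hit)) {
      abort(paste0("coupling references unknown line: state ", cp$state,
                   " at ", cp$energy_eV, " eV."),
            class = "trxps_config_error")
    }
  }
  tidyr::crossing(t = tg, sticks) |>
    dplyr::group_by(.data$state, .data$energy) |>
    dplyr::mutate(energy_t = .data$energy +
                    shift_of(.data$state[1], .data$energy[1])) |>
    dplyr::ungroup() |>
    dplyr::mutate(energy_base = .data$energy, energy = .data$energy_t) |>
    dplyr::select(-"energy_t")
}

#' Pump-probe sideband contribution
#'
#' During temporal overlap of the UV and X-ray pulses, every ground-state
#' line acquires replicas displaced by plus/minus one UV photon energy
#' (absorption or stimulated emission of a pump photon together with the
#' X-ray ionization). The replica amplitude is
#' `ratio * f * exp(-(t - t0)^2 / (2 sigma_cc^2))` per sideband, so the peak
#' of the low-energy sideband is `ratio` times the asymptotic depletion of
#' the main line; the borrowed intensity is removed from the main line so
#' total counts are conserved.
#'
#' @param gs_spectrum Broadened GS spectrum tibble (columns `energy`,
#'   `intensity`) on the evaluation grid.
#' @param pump_energy UV photon energy (eV).
#' @param t Scalar delay (fs).
#' @param t0,sigma_cc Cross-correlation centre and Gaussian sigma (fs).
#' @param ratio Sideband amplitude ratio (>= 0); `f` is folded in by the
#'   caller via `amplitude_scale`.
#' @param amplitude_scale Overall scale multiplying the Gaussian gate
#'   (default 1), e.g. the excited fraction `f`.
#' @param upper_factor Relative amplitude of the high-energy replica.
#' @return A tibble `energy`, `intensity` of the *signed* sideband
#'   contribution (replicas positive, main-line borrowing negative).
#' @export
sideband_component <- function(gs_spectrum, pump_energy, t, t0, sigma_cc,
                               ratio, amplitude_scale = 1,
                               upper_factor = 1) {
  if (ratio < 0) abort("`ratio` must be >= 0.", class = "trxps_domain_error")
  gate <- exp(-(t - t0)^2 / (2 * sigma_cc^2))
  a <- ratio * amplitude_scale * gate
  x <- gs_spectrum$energy
  y <- gs_spectrum$intensity
  shift_interp <- function(d) {
    approx(x, y, xout = x - d, yleft = 0, yright = 0)$y
  }
  lower <- a * shift_interp(-pump_energy)
  upper <- a * upper_factor * shift_interp(+pump_energy)
  tibble::tibble(energy = x,
                 intensity = lower + upper - (a + a * upper_factor) * y)
}

delay_schedule <- function(instrument) {
  c(seq(instrument$delay_dense_min, instrument$delay_dense_max,
        by = instrument$delay_dense_step),
    instrument$long_delays)
}

# expected (noise-free) count densities for one edge; returns list with
# matrices on (grid x delays) and off, plus bookkeeping.
expected_maps <- function(config) {
  ins <- config$instrument
  kin <- do.call(kinetic_params, config$kinetics)
  grid <- seq(ins$be_min, ins$be_max, by = ins$be_step)
  delays <- config$delays %||% delay_schedule(ins)
  shape <- lineshape(ins$lineshape_kind, ins$lineshape_fwhm)

  sticks <- load_stick_tables(ins$edge)
  gs <- apply_rigid_shift(sticks[sticks$state == "GS", ], ins$rigid_shift_eV)
  exc <- apply_rigid_shift(sticks[sticks$state != "GS", ], ins$rigid_shift_eV)
  trip <- config$spectra$triplet_lines %||% default_triplet_sticks(ins$edge)
  gs_area <- sum(gs$strength)

  delays <- sort(delays)
  pops <- populations(kin, delays)

  bonds <- simulate_bond_series(config$vibration$modes, delays,
                                unlist(config$vibration$equilibrium))
  dev <- tidyr::pivot_wider(bonds, names_from = "bond",
                            values_from = "length")

  gs_dens <- broaden(gs, shape, grid)$intensity

  # per-state stick lists with per-delay energies
  state_lines <- list(
    S2_pipi = exc[exc$state == "S2_pipi", ],
    S1_npi  = exc[exc$state == "S1_npi", ],
    T_pipi  = trip[trip$state == "T_pipi", ],
    T_npi   = trip[trip$state == "T_npi", ]
  )
  scale_of <- purrr::map_dbl(state_lines, ~ gs_area / sum(.x$strength))

  coupl <- config$vibration$couplings %||% list()
  eqm <- unlist(config$vibration$equilibrium)
  line_shift <- function(state, base_energy_table) {
    # vector over delays
    total <- rep(0, length(delays))
    for (cp in coupl) {
      # table lines are identified by their (shifted) table energy; synthetic
      # lines (triplets) already live on the experimental scale
      if (cp$state == state &&
          (abs(cp$energy_eV + ins$rigid_shift_eV - base_energy_table) < 1e-6 ||
           abs(cp$energy_eV - base_energy_table) < 1e-6)) {
        total <- total + cp$slope_eV_per_A *
          (dev[[cp$bond]] - unname(eqm[[cp$bond]]))
      }
    }
    if (state == "S2_pipi" && (config$spectra$s2_drift_eV %||% 0) != 0) {
      ramp <- pmin(pmax(delays, 0) / config$spectra$s2_drift_fs, 1)
      total <- total + config$spectra$s2_drift_eV * ramp
    }
    total
  }

  hgs_cfg <- config$spectra$hgs
  hgs_center0 <- sum(gs$energy * gs$strength) / gs_area
  hgs_offset <- hgs_cfg$offset_max_eV *
    pmin(pmax(delays, 0) / hgs_cfg$t_sat_fs, 1)
  hgs_osc <- if (!is.null(hgs_cfg$osc_bond) &&
                 hgs_cfg$osc_bond %in% names(dev)) {
    (config$vibration$hgs_coupling_eV_per_A %||% 0) *
      (dev[[hgs_cfg$osc_bond]] - unname(eqm[[hgs_cfg$osc_bond]]))
  } else rep(0, length(delays))
  hgs_centers <- hgs_center0 + hgs_offset + hgs_osc

  sb_ratio <- ins$sideband_ratio
  sb_up <- ins$sideband_upper_factor %||% 1
  gate <- exp(-(delays - kin$t0)^2 / (2 * kin$sigma_irf^2))
  a_low <- sb_ratio * kin$f * gate
  a_up <- a_low * sb_up

  sb_low_dens <- broaden(
    dplyr::mutate(gs, energy = .data$energy - ins$pump_energy_eV),
    shape, grid)$intensity
  sb_up_dens <- broaden(
    dplyr::mutate(gs, energy = .data$energy + ins$pump_energy_eV),
    shape, grid)$intensity

  nx <- length(grid); nt <- length(delays)
  on <- matrix(0, nx, nt)
  state_pop <- list(S2_pipi = pops$p_s2, S1_npi = pops$p_s1,
                    T_pipi = pops$p_t * 0.5, T_npi = pops$p_t * 0.5)
  C <- pnorm(delays, kin$t0, kin$sigma_irf)
  for (j in seq_len(nt)) {
    dens <- gs_dens * (1 - kin$f * C[j] - a_low[j] - a_up[j]) +
      a_low[j] * sb_low_dens + a_up[j] * sb_up_dens
    for (s in names(state_lines)) {
      p <- state_pop[[s]][j]
      if (p <= 0) next
      lines <- state_lines[[s]]
      if (nrow(lines) == 0) next
      e_t <- lines$energy +
        purrr::map_dbl(seq_len(nrow(lines)),
                       ~ line_shift(s, lines$energy[.x])[j])
      for (i in seq_len(nrow(lines))) {
        dens <- dens + p * scale_of[[s]] * lines$strength[i] *
          lineshape_density(grid - e_t[i], shape)
      }
    }
    if (pops$p_hgs[j] > 0) {
      dens <- dens + pops$p_hgs[j] * gs_area *
        skew_normal_density(grid, hgs_centers[j], hgs_cfg$sigma_eV,
                            hgs_cfg$asymmetry)
    }
    on[, j] <- dens
  }
  off <- matrix(gs_dens, nx, nt)
  K <- ins$counts_scale / max(gs_dens)
  list(grid = grid, delays = delays, on = on * K, off = off * K,
       kin = kin, gs_dens = gs_dens * K, pops = pops, bonds = bonds)
}

#' Generate a synthetic UV-on / UV-off map pair
#'
#' Builds the expected TR-XPS count maps for the configured edge (state
#' spectra weighted by the closed-form populations, full ground-state
#' depletion, hot-ground-state line, pump-probe sidebands gated by the
#' cross-correlation, coherent line-position modulation) and, unless
#' `noise = FALSE`, draws independent Poisson counts per (binding energy,
#' delay) pixel. The complete generator parameter record is attached as the
#' `truth` attribute, and a fixed seed gives bit-identical output.
#'
#' @param config A pipeline configuration, e.g. from [preset()].
#' @param noise Draw Poisson counts (default `TRUE`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `trxps_map_pair`: tibble with columns `delay`, `energy`, `on`,
#'   `off` and attributes `truth`, `edge`, `seed`.
#' @export
#' @examples
#' pair <- generate_map_pair(preset("fast_smoke"))
generate_map_pair <- function(config, noise = TRUE, seed = NULL) {
  config <- validate_config(config)
  seed <- seed %||% config$seed %||% 1L
  em <- expected_maps(config)
  on <- em$on
  off <- em$off
  if (noise) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    on <- matrix(rpois(length(on), lambda = on), nrow(on), ncol(on))
    off <- matrix(rpois(length(off), lambda = off), nrow(off), ncol(off))
  }
  out <- tibble::tibble(
    delay = rep(em$delays, each = length(em$grid)),
    energy = rep(em$grid, times = length(em$delays)),
    on = as.numeric(on),
    off = as.numeric(off)
  )
  truth <- list(
    config = config, seed = seed, noise = noise,
    f = em$kin$f, phi_hgs = em$kin$phi_hgs,
    tau_ic = em$kin$tau_ic, tau_isc = em$kin$tau_isc,
    t0 = em$kin$t0, cc_fwhm = em$kin$cc_fwhm, sigma_irf = em$kin$sigma_irf,
    irf_convention = "fwhm",
    oscillation_assignment = config$oscillation_assignment
  )
  structure(out, class = c("trxps_map_pair", class(out)),
            truth = truth, edge = config$instrument$edge, seed = seed)
}

#' Generator truth record
#'
#' @param pair A `trxps_map_pair`.
#' @return The truth parameter record attached by [generate_map_pair()].
#' @export
map_truth <- function(pair) attr(pair, "truth")

#' Rebin per-shot spectra onto a regular delay grid
#'
#' Emulates the arrival-time correction workflow: shots carrying corrected
#' (jittered) delays are assigned to bins of `bin_width` fs; counts are
#' summed per bin and energy, the reported bin delay is the count-weighted
#' mean corrected delay, and total counts are conserved. Empty bins are
#' dropped with a notice.
#'
#' @param shots Tibble with columns `delay`, `energy`, `counts`.
#' @param bin_width Bin width in fs (> 0), default 18.
#' @return Tibble with columns `delay` (weighted bin centre), `energy`,
#'   `counts`.
#' @export
rebin_delays <- function(shots, bin_width = 18) {
  check_positive(bin_width, "bin_width")
  lo <- min(shots$delay)
  shots$bin <- floor((shots$delay - lo) / bin_width)
  n_possible <- max(shots$bin) + 1
  n_used <- length(unique(shots$bin))
  if (n_used < n_possible) {
    message(n_possible - n_used, " empty delay bin(s) dropped")
  }
  per_shot <- shots |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(.w = sum(.data$counts)) |>
    dplyr::ungroup()
  per_shot |>
    dplyr::group_by(.data$bin, .data$energy) |>
    dplyr::summarise(
      delay = sum(.data$delay * .data$counts) / sum(.data$counts),
      counts = sum(.data$counts), .groups = "drop_last") |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(delay = sum(.data$delay * .data$counts) /
                    sum(.data$counts)) |>
    dplyr::ungroup() |>
    dplyr::select("delay", "energy", "counts") |>
    dplyr::arrange(.data$delay, .data$energy)
}
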
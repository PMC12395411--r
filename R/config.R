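#' Default pipeline configuration
#'
#' Nested configuration driving the generator and the analysis pipeline.
#' Defaults encode the study conditions of the uracil TR-XPS experiment:
#' 264 nm (4.70 eV) pump, 80.5 fs fwhm cross-correlation, 17 fs internal
#' conversion, 1.6 ps intersystem crossing, 36% instantaneous
#' hot-ground-state branch, excited fraction f = 0.09, 18 fs delay bins on
#' a -200..+500 fs dense scan plus 1 ps-1 ns fixed delays, sideband ratios
#' 0.23 (O 1s) / 1.3 (N 1s), rigid theory-to-experiment shifts -2.4 eV
#' (O 1s) / -2.1 eV (N 1s), and coherent modes at 114.6, 198.1 and
#' 292.7 cm^-1 with 0.1 A amplitudes.
#'
#' @param edge `"O1s"` or `"N1s"`.
#' @return A named nested list.
#' @export
default_config <- function(edge = c("O1s", "N1s")) {
  edge <- match.arg(edge)
  o1s <- edge == "O1s"
  list(
    instrument = list(
      edge = edge,
      be_min = if (o1s) 528 else 396.5,
      be_max = if (o1s) 550 else 417,
      be_step = 0.02,
      delay_dense_min = -200,
      delay_dense_max = 500,
      delay_dense_step = 20,
      long_delays = c(1e3, 1e4, 1e5, 1e6),
      bin_width_fs = 18,
      counts_scale = 1e4,
      sideband_ratio = if (o1s) 0.23 else 1.3,
      sideband_upper_factor = 1,
      pump_energy_eV = 4.70,
      jitter_sigma_fs = 0,
      rigid_shift_eV = if (o1s) -2.4 else -2.1,
      lineshape_kind = "gaussian",
      lineshape_fwhm = if (o1s) 0.8 else 1.0
    ),
    kinetics = list(
      t0 = 0, cc_fwhm = 80.5, tau_ic = 17, tau_isc = 1600,
      phi_hgs = 0.36, f = 0.09
    ),
    spectra = list(
      s2_drift_eV = 0,
      s2_drift_fs = 25,
      hgs = list(
        offset_max_eV = 0.3, t_sat_fs = 1000,
        sigma_eV = fwhm_to_sigma(1.6), asymmetry = 0.3,
        osc_bond = "ring"
      ),
      triplet_lines = NULL
    ),
    vibration = list(
      modes = list(
        list(freq_cm1 = 114.6, bond = "ring", amp_A = 0.1,
             damp_fs = 700, phase = 0),
        list(freq_cm1 = 198.1, bond = "C4O8", amp_A = 0.1,
             damp_fs = 600, phase = 0),
        list(freq_cm1 = 292.7, bond = "C5C6", amp_A = 0.1,
             damp_fs = 600, phase = 0)
      ),
      equilibrium = list(C4O8 = 1.22, C5C6 = 1.34, ring = 1.40),
      couplings = if (o1s) list(
        list(state = "S1_npi", energy_eV = 544.02, bond = "C5C6",
             slope_eV_per_A = 2.0),
        list(state = "T_pipi", energy_eV = 540.6, bond = "C4O8",
             slope_eV_per_A = 2.0)
      ) else list(),
      hgs_coupling_eV_per_A = 1.5
    ),
    regions = default_regions(edge),
    fit = list(
      regions = if (o1s) c("SB", "A", "C", "D", "E") else c("A", "B"),
      components = NULL,  # NULL -> default_fit_components()
      tau_ic_bounds = c(1, 500),
      tau_isc_bounds = c(100, 1e5),
      tau_ic_init = 50,
      tau_isc_init = 1000
    ),
    analysis = list(
      gs_window = if (o1s) c(536.0, 539.0) else c(405.8, 408.0),
      f_delay_window = c(200, 450),
      model_based_f = TRUE,
      track_window = if (o1s) c(536, 539.4) else c(405, 408.5)
    ),
    fft = list(
      window = "hann", pad_factor = 8, band_cm1 = c(50, 900)
    ),
    oscillation_assignment = if (o1s)
      list(C = 114.6, D = 292.7, E = 292.7) else list(),
    delays = NULL,
    seed = 1L
  )
}

check_known_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra) > 0) {
    abort(paste0("unknown configuration key", if (length(extra) > 1) "s",
                 ": ", paste0(path, extra, collapse = ", ")),
          class = "trxps_config_error")
  }
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]])) &&
        is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      check_known_keys(cfg[[k]], template[[k]], paste0(path, k, "$"))
    }
  }
  invisible(cfg)
}

#' Validate and complete a pipeline configuration
#'
#' Fills unset fields from [default_config()] and rejects unknown keys with
#' a message naming the offending key.
#'
#' @param config A (possibly partial) configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  if (isTRUE(attr(config, "validated"))) return(config)
  edge <- config$instrument$edge %||% "O1s"
  template <- default_config(edge)
  check_known_keys(config, template)
  merge_cfg <- function(tmpl, cfg) {
    for (k in names(cfg)) {
      recurse <- is.list(cfg[[k]]) && is.list(tmpl[[k]]) &&
        !is.null(names(cfg[[k]])) && !is.null(names(tmpl[[k]])) &&
        !is.data.frame(cfg[[k]]) && !is.data.frame(tmpl[[k]])
      if (recurse) {
        tmpl[[k]] <- merge_cfg(tmpl[[k]], cfg[[k]])
      } else {
        tmpl[k] <- list(cfg[[k]])  # wholesale (preserves NULL, unnamed lists)
      }
    }
    tmpl
  }
  out <- merge_cfg(template, config)
  kin <- out$kinetics
  do.call(kinetic_params, kin) # validates ranges
  check_positive(out$instrument$bin_width_fs, "bin_width_fs")
  check_positive(out$instrument$counts_scale, "counts_scale")
  attr(out, "validated") <- TRUE
  out
}

#' Scenario presets
#'
#' Complete pipeline configurations with fixed seeds, regenerating identical
#' synthetic maps:
#' \describe{
#' \item{o1s_paper}{O 1s at the reported study conditions: tau_ic 17 fs,
#'   tau_isc 1.6 ps, cross-correlation 80.5 fs fwhm, f 0.09, phi 0.36,
#'   sideband ratio 0.23, modes 114.6/198.1/292.7 cm^-1 at 0.1 A.}
#' \item{n1s_paper}{N 1s analogue with sideband ratio 1.3.}
#' \item{fast_smoke}{Coarse grids for quick checks.}
#' \item{degenerate_taus}{tau_ic = tau_isc, exercising the analytic
#'   degenerate sequential-filling branch.}
#' \item{no_vibration}{All coherent mode amplitudes zero.}
#' }
#'
#' @param name Preset name.
#' @return A validated configuration list.
#' @export
#' @examples
#' cfg <- preset("fast_smoke")
preset <- function(name = c("o1s_paper", "n1s_paper", "fast_smoke",
                            "degenerate_taus", "no_vibration")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    abort(paste0("unknown preset `", name[1], "`."),
          class = "trxps_lookup_error")
  })
  cfg <- switch(name,
    o1s_paper = {
      x <- default_config("O1s"); x$seed <- 101L; x
    },
    n1s_paper = {
      x <- default_config("N1s"); x$seed <- 201L; x
    },
    fast_smoke = {
      x <- default_config("O1s")
      x$instrument$be_step <- 0.1
      x$instrument$delay_dense_step <- 50
      x$instrument$counts_scale <- 2000
      x$seed <- 301L
      x
    },
    degenerate_taus = {
      x <- default_config("O1s")
      x$kinetics$tau_ic <- 300
      x$kinetics$tau_isc <- 300
      x$seed <- 401L
      x
    },
    no_vibration = {
      x <- default_config("O1s")
      x$vibration$modes <- purrr::map(x$vibration$modes, function(m) {
        m$amp_A <- 0; m
      })
      x$spectra$hgs$osc_bond <- NULL
      x$oscillation_assignment <- list()
      x$seed <- 501L
      x
    }
  )
  cfg$preset <- NULL
  out <- validate_config(cfg)
  attr(out, "preset") <- name
  out
}
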
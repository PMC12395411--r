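#' Default binding-energy integration regions
#'
#' Half-open intervals `[lo, hi)` on the experimental binding-energy axis.
#' O 1s: the published regions A-F plus a low-energy sideband window `SB`
#' centred on the 532.9 eV feature; N 1s: regions A and B.
#'
#' @param edge `"O1s"` or `"N1s"`.
#' @return A tibble with columns `region`, `lo`, `hi`.
#' @export
default_regions <- function(edge = c("O1s", "N1s")) {
  edge <- match.arg(edge)
  if (edge == "O1s") {
    tibble::tribble(
      ~region, ~lo, ~hi,
      "SB", 531.5, 533.5,
      "A", 535.9, 536.6,
      "B", 537.2, 538.0,
      "C", 539.0, 540.0,
      "D", 540.1, 541.5,
      "E", 541.6, 543.5,
      "F", 544.5, 547.5
    )
  } else {
    tibble::tribble(
      ~region, ~lo, ~hi,
      "A", 404.8, 406.0,
      "B", 406.3, 408.3
    )
  }
}

check_pair <- function(pair) {
  need <- c("delay", "energy", "on", "off")
  if (!all(need %in% names(pair))) {
    abort("expected a map pair with columns delay, energy, on, off.",
          class = "trxps_data_error")
  }
  invisible(pair)
}

#' Pixelwise difference map
#'
#' UV-on minus UV-off, with Poisson uncertainties added in quadrature:
#' excited-state features appear positive, ground-state depletion negative.
#'
#' @param pair A `trxps_map_pair` (columns `delay`, `energy`, `on`, `off`),
#'   or two separate long-format maps via `on`/`off`.
#' @return A tibble `delay`, `energy`, `diff`, `sigma`.
#' @export
difference_map <- function(pair) {
  check_pair(pair)
  tibble::tibble(
    delay = pair$delay, energy = pair$energy,
    diff = pair$on - pair$off,
    sigma = sqrt(pmax(pair$on, 0) + pmax(pair$off, 0))
  )
}

#' Scaled subtraction of the ground-state contribution
#'
#' Removes the (1 - f) ground-state fraction from the UV-on map and rescales
#' to a per-excited-molecule spectrum: `[on - (1 - f) off] / f`, pixelwise,
#' with propagated Poisson uncertainties. With the correct `f` the
#' ground-state depletion feature is eliminated.
#'
#' @param pair Map pair.
#' @param f Excited fraction, in (0, 1].
#' @return A tibble `delay`, `energy`, `value`, `sigma`.
#' @export
scaled_subtract <- function(pair, f) {
  check_pair(pair)
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f > 1) {
    abort("`f` must be in (0, 1].", class = "trxps_domain_error")
  }
  tibble::tibble(
    delay = pair$delay, energy = pair$energy,
    value = (pair$on - (1 - f) * pair$off) / f,
    sigma = sqrt(pmax(pair$on, 0) + (1 - f)^2 * pmax(pair$off, 0)) / f
  )
}

#' Estimate the excited-state fraction by scaled subtraction
#'
#' Chooses `f` so that `on - (1 - f) off` inside a ground-state
#' binding-energy window, over a late-delay window, is as close to zero as
#' possible in the least-squares sense while remaining non-negative
#' (negative depletion features are eliminated, positive excited-state
#' features are allowed). Uncertainty is the curvature-based standard error
#' of the least-squares estimate.
#'
#' When excited-state or hot-ground-state intensity overlaps the
#' ground-state window (as it does for uracil O 1s, where the S1 O7 line
#' lies ~0.1 eV from the GS lines and the hot ground state sits under the
#' main peak), a plain window estimator is biased. Supplying
#' `components` - non-negative contaminant spectra, typically built with
#' [f_estimator_components()] from the package's own spectral model - fits
#' them alongside `(1 - f) off` and removes that bias; this is the variant
#' the pipeline uses, and it is flagged in the result.
#'
#' @param pair Map pair.
#' @param gs_window Numeric `c(lo, hi)` eV, the ground-state window.
#' @param delay_window Numeric `c(lo, hi)` fs, after temporal overlap.
#' @param components Optional matrix/data frame of contaminant spectra
#'   evaluated on the window's energy grid (one column per component), or
#'   `NULL` for the plain estimator.
#' @return A one-row tibble `f`, `sigma_f`, `method`.
#' @export
estimate_excited_fraction <- function(pair, gs_window = c(536.0, 539.0),
                                      delay_window = c(200, 450),
                                      components = NULL) {
  check_pair(pair)
  sel <- pair$energy >= gs_window[1] & pair$energy < gs_window[2] &
    pair$delay >= delay_window[1] & pair$delay <= delay_window[2]
  sub <- pair[sel, , drop = FALSE]
  if (nrow(sub) == 0 || sum(sub$off) <= 0) {
    abort("degenerate estimation window: no off-signal.",
          class = "trxps_estimation_error")
  }
  if (is.null(components)) {
    # minimize || on - (1-f) off ||^2 -> closed form, then enforce
    # non-negativity of the delay-averaged subtracted spectrum
    f_ls <- 1 - sum(sub$on * sub$off) / sum(sub$off^2)
    avg <- sub |>
      dplyr::group_by(.data$energy) |>
      dplyr::summarise(on = mean(.data$on), off = mean(.data$off),
                       n = dplyr::n(), .groups = "drop")
    # non-negativity of the delay-averaged subtracted spectrum, with a
    # 2-sigma Poisson allowance, on pixels carrying real off-signal (the
    # max statistic over near-empty tail pixels is fat-tailed otherwise)
    ok <- avg$off >= pmax(0.05 * max(avg$off), 1)
    f_feas <- if (any(ok)) {
      allow <- 2 * sqrt((pmax(avg$on[ok], 1) + avg$off[ok]) / avg$n[ok])
      max(1 - (avg$on[ok] + allow) / avg$off[ok])
    } else -Inf
    f_hat <- min(max(f_ls, f_feas, 0), 1)
    sigma_f <- sqrt(sum(sub$off^2 * (pmax(sub$on, 0) +
                                       (1 - f_hat)^2 * pmax(sub$off, 0)))) /
      sum(sub$off^2)
    method <- "windowed least squares (non-negativity constrained)"
  } else {
    comp <- as.matrix(components)
    egrid <- sort(unique(sub$energy))
    if (nrow(comp) != length(egrid)) {
      abort("`components` rows must match the window's energy grid.",
            class = "trxps_alignment_error")
    }
    delays <- unique(sub$delay)
    num <- 0; den <- 0
    for (d in delays) {
      sd_ <- sub[sub$delay == d, ]
      sd_ <- sd_[order(sd_$energy), ]
      X <- cbind(off = sd_$off, comp)
      # NNLS: coefficients >= 0; c_off = (1 - f) <= 1 holds when f >= 0
      fit <- pracma::lsqnonneg(X, sd_$on)
      c_off <- fit$x[1]
      w <- sum(sd_$off^2)
      num <- num + w * (1 - c_off)
      den <- den + w
    }
    f_hat <- min(max(num / den, 0), 1)
    sigma_f <- sqrt(sum(sub$off^2 * (pmax(sub$on, 0) +
                                       (1 - f_hat)^2 * pmax(sub$off, 0)))) /
      sum(sub$off^2)
    method <- "model-based scaled subtraction (NNLS contaminants)"
  }
  tibble::tibble(f = f_hat, sigma_f = sigma_f, method = method)
}

#' Contaminant spectra for the model-based excited-fraction estimator
#'
#' Evaluates the package's spectral model of the excited-state and
#' hot-ground-state contributions on the energy grid of a window, for use as
#' `components` in [estimate_excited_fraction()].
#'
#' @param config Pipeline configuration (for the edge, shift, lineshape and
#'   hot-ground-state parameters).
#' @param energy_grid Energies (eV) of the window.
#' @return A matrix with one column per contaminant state.
#' @export
f_estimator_components <- function(config, energy_grid) {
  ins <- config$instrument
  shape <- lineshape(ins$lineshape_kind, ins$lineshape_fwhm)
  sticks <- load_stick_tables(ins$edge)
  exc <- apply_rigid_shift(sticks[sticks$state != "GS", ],
                           ins$rigid_shift_eV)
  trip <- config$spectra$triplet_lines %||% default_triplet_sticks(ins$edge)
  gs <- apply_rigid_shift(sticks[sticks$state == "GS", ],
                          ins$rigid_shift_eV)
  hgs_cfg <- config$spectra$hgs
  center0 <- sum(gs$energy * gs$strength) / sum(gs$strength)
  cols <- list(
    S1 = broaden(exc[exc$state == "S1_npi", ], shape, energy_grid,
                 check_coverage = FALSE)$intensity,
    S2 = broaden(exc[exc$state == "S2_pipi", ], shape, energy_grid,
                 check_coverage = FALSE)$intensity,
    T = broaden(trip, shape, energy_grid, check_coverage = FALSE)$intensity,
    HGS = skew_normal_density(energy_grid,
                              center0 + hgs_cfg$offset_max_eV / 2,
                              hgs_cfg$sigma_eV, hgs_cfg$asymmetry)
  )
  do.call(cbind, cols)
}

#' Integrate a map into per-region time traces
#'
#' Sums pixel values with binding energy in each half-open region
#' `[lo, hi)`, per delay, with Poisson uncertainties combined in quadrature.
#'
#' @param map Long-format map: either a difference map (`diff`/`sigma`), a
#'   scaled-subtracted map (`value`/`sigma`), a map pair (integrates
#'   `on - off`), or any tibble with `delay`, `energy` and one value column
#'   named by `value_col`.
#' @param regions Region tibble (`region`, `lo`, `hi`), e.g.
#'   [default_regions()].
#' @param value_col Name of the value column; auto-detected by default.
#' @return A `trxps_traces` tibble: `region`, `delay`, `value`, `sigma`.
#' @export
integrate_regions <- function(map, regions, value_col = NULL) {
  if (all(c("on", "off") %in% names(map))) map <- difference_map(map)
  value_col <- value_col %||%
    intersect(c("diff", "value", "counts"), names(map))[1]
  if (is.na(value_col) || is.null(value_col)) {
    abort("no value column found.", class = "trxps_data_error")
  }
  has_sigma <- "sigma" %in% names(map)
  out <- purrr::pmap(regions, function(region, lo, hi) {
    sel <- map$energy >= lo & map$energy < hi
    if (!any(sel)) {
      abort(paste0("region ", region, " [", lo, ", ", hi,
                   ") contains no grid points."),
            class = "trxps_config_error")
    }
    sub <- map[sel, ]
    sub |>
      dplyr::group_by(.data$delay) |>
      dplyr::summarise(
        value = sum(.data[[value_col]]),
        sigma = if (has_sigma) sqrt(sum(.data$sigma^2)) else NA_real_,
        .groups = "drop") |>
      dplyr::mutate(region = region, .before = 1)
  }) |>
    dplyr::bind_rows()
  structure(out, class = c("trxps_traces", class(out)))
}

#' Sideband-corrected depletion trace
#'
#' Adds the sideband trace back onto the depletion trace (elementwise, with
#' uncertainties in quadrature). During pulse overlap the sidebands borrow
#' intensity from the main line, deepening the apparent depletion; the
#' correction restores the monotone depletion trend (prominent for N 1s,
#' where the sideband ratio is large).
#'
#' @param depletion_trace,sb_trace Tibbles with `delay`, `value`, `sigma`
#'   on identical delay grids.
#' @return Tibble `delay`, `value`, `sigma`.
#' @export
sideband_corrected_depletion <- function(depletion_trace, sb_trace) {
  if (nrow(depletion_trace) != nrow(sb_trace) ||
      max(abs(depletion_trace$delay - sb_trace$delay)) > 1e-9) {
    abort("traces are not on the same delay grid.",
          class = "trxps_alignment_error")
  }
  tibble::tibble(
    delay = depletion_trace$delay,
    value = depletion_trace$value + sb_trace$value,
    sigma = sqrt(depletion_trace$sigma^2 + sb_trace$sigma^2)
  )
}

# separable Gaussian smoothing of a map in (energy, delay); sigma = 0 skips
# the corresponding axis. Operates on a wide matrix internally.
smooth_map <- function(map, value_col, sigma_t = 0, sigma_e = 0) {
  wide <- tidyr::pivot_wider(map[, c("delay", "energy", value_col)],
                             names_from = "delay",
                             values_from = dplyr::all_of(value_col))
  egrid <- wide$energy
  m <- as.matrix(wide[, -1])
  tgrid <- as.numeric(colnames(m))
  gauss_smooth <- function(v, x, sigma) {
    if (sigma <= 0) return(v)
    vapply(seq_along(x), function(i) {
      w <- dnorm(x - x[i], sd = sigma)
      sum(w * v) / sum(w)
    }, numeric(1))
  }
  m <- apply(m, 2, gauss_smooth, x = egrid, sigma = sigma_e)
  m <- t(apply(m, 1, gauss_smooth, x = tgrid, sigma = sigma_t))
  list(energy = egrid, delay = tgrid, values = m)
}

# Gaussian + linear baseline fit on one spectrum; returns named list or NULL
fit_gauss_baseline <- function(x, y) {
  ymin <- min(y); yr <- diff(range(y))
  if (yr <= 0) return(NULL)
  mu0 <- x[which.max(y)]
  s0 <- max(diff(range(x)) / 8, 1e-3)
  fit <- tryCatch(
    suppressWarnings(
      nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + b0 + b1 * x,
          start = list(A = yr, mu = mu0, s = s0,
                       b0 = ymin, b1 = 0),
          control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(coef(fit)))) return(NULL)
  cf <- coef(fit)
  list(mean = unname(cf["mu"]), sigma_width = abs(unname(cf["s"])),
       amplitude = unname(cf["A"]), baseline_intercept = unname(cf["b0"]),
       baseline_slope = unname(cf["b1"]),
       resid_norm = sqrt(sum(stats::residuals(fit)^2)))
}

#' Track the ground-state peak across delays
#'
#' Per delay bin, fits a Gaussian plus linear baseline to the (optionally
#' Gaussian-smoothed) spectrum inside the window, returning the fitted mean,
#' sigma width, amplitude and baseline, plus the position of the smoothed
#' maximum as a separate series. Non-convergent bins are flagged, not fatal.
#'
#' @param map Long-format map with a single value column (e.g. a
#'   scaled-subtracted map); pairs are reduced with [scaled_subtract()]
#'   first by the caller.
#' @param window Energy window `c(lo, hi)` eV (default 536-539.4).
#' @param smooth_sigma_t,smooth_sigma_e Gaussian filter sigmas along delay
#'   (fs) and energy (eV) applied before locating the smoothed maximum
#'   (defaults 18 fs and 0.2 eV); zero disables smoothing. The
#'   Gaussian+baseline fit itself uses the unsmoothed spectra.
#' @param value_col Value column name (auto-detected).
#' @return A `trxps_peaktrack` tibble: `delay`, `mean`, `sigma_width`,
#'   `amplitude`, `baseline_intercept`, `baseline_slope`, `resid_norm`,
#'   `smoothed_max`, `converged`.
#' @export
track_gs_peak <- function(map, window = c(536, 539.4),
                          smooth_sigma_t = 18, smooth_sigma_e = 0.2,
                          value_col = NULL) {
  value_col <- value_col %||%
    intersect(c("value", "diff", "counts", "on"), names(map))[1]
  sel <- map$energy >= window[1] & map$energy <= window[2]
  if (!any(sel)) {
    abort("window outside map grid.", class = "trxps_config_error")
  }
  sub <- map[sel, ]
  sm <- smooth_map(sub, value_col, smooth_sigma_t, smooth_sigma_e)
  raw <- smooth_map(sub, value_col, 0, 0)
  out <- purrr::map(seq_along(raw$delay), function(j) {
    fit <- fit_gauss_baseline(raw$energy, raw$values[, j])
    smax <- sm$energy[which.max(sm$values[, j])]
    if (is.null(fit)) {
      tibble::tibble(delay = raw$delay[j], mean = NA_real_,
                     sigma_width = NA_real_, amplitude = NA_real_,
                     baseline_intercept = NA_real_, baseline_slope = NA_real_,
                     resid_norm = NA_real_, smoothed_max = smax,
                     converged = FALSE)
    } else {
      tibble::tibble(delay = raw$delay[j], mean = fit$mean,
                     sigma_width = fit$sigma_width,
                     amplitude = fit$amplitude,
                     baseline_intercept = fit$baseline_intercept,
                     baseline_slope = fit$baseline_slope,
                     resid_norm = fit$resid_norm, smoothed_max = smax,
                     converged = TRUE)
    }
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$delay)
  structure(out, class = c("trxps_peaktrack", class(out)))
}

#' Time-windowed, energy-smoothed spectra
#'
#' For each requested centre, averages the map over a delay interval of the
#' given width, smooths the result along energy with a Gaussian filter, and
#' reports the maximum position.
#'
#' @param map Long-format map with one value column.
#' @param centers Delay centres (fs).
#' @param width Window width (fs), default 108.
#' @param smooth_sigma Energy smoothing sigma (eV), default 0.15.
#' @param value_col Value column name (auto-detected).
#' @return A tibble `center`, `energy`, `value` plus attribute `maxima`
#'   (tibble `center`, `max_energy`).
#' @export
windowed_spectra <- function(map, centers, width = 108, smooth_sigma = 0.15,
                             value_col = NULL) {
  value_col <- value_col %||%
    intersect(c("value", "diff", "counts", "on"), names(map))[1]
  out <- purrr::map(centers, function(ct) {
    sel <- map$delay >= ct - width / 2 & map$delay <= ct + width / 2
    if (!any(sel)) {
      abort(paste0("empty delay interval around ", ct, " fs."),
            class = "trxps_config_error")
    }
    sp <- map[sel, ] |>
      dplyr::group_by(.data$energy) |>
      dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop")
    if (smooth_sigma > 0) {
      v <- vapply(seq_len(nrow(sp)), function(i) {
        w <- dnorm(sp$energy - sp$energy[i], sd = smooth_sigma)
        sum(w * sp$value) / sum(w)
      }, numeric(1))
      sp$value <- v
    }
    dplyr::mutate(sp, center = ct, .before = 1)
  }) |>
    dplyr::bind_rows()
  maxima <- out |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(max_energy = .data$energy[which.max(.data$value)],
                     .groups = "drop")
  attr(out, "maxima") <- maxima
  out
}
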
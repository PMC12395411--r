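#' Detrend a time trace against a kinetic model prediction
#'
#' Residual = trace minus model prediction, mean-centred; this removes the
#' population dynamics before Fourier analysis of the coherent oscillations.
#'
#' @param trace Tibble `delay`, `value`.
#' @param prediction Numeric vector of model values on the same grid, or a
#'   tibble with `delay`, `fitted`.
#' @return Tibble `delay`, `residual`.
#' @export
detrend_trace <- function(trace, prediction) {
  pred <- if (is.data.frame(prediction)) {
    if (nrow(prediction) != nrow(trace) ||
        max(abs(prediction$delay - trace$delay)) > 1e-9) {
      abort("prediction is not aligned with the trace.",
            class = "trxps_alignment_error")
    }
    prediction$fitted
  } else prediction
  r <- trace$value - pred
  tibble::tibble(delay = trace$delay, residual = r - mean(r))
}

#' Fourier spectrum of a residual trace
#'
#' Resamples the residual onto a uniform grid (linear interpolation at the
#' nominal bin width), applies an apodization window, zero-pads, and returns
#' the magnitude spectrum with the frequency axis in cm^-1. Long-delay
#' points (>= 1 ps) are excluded (non-uniform sampling); peaks are local
#' maxima above a noise-floor estimate inside the analysis band.
#'
#' With an ~650 fs record the raw resolution is ~51 cm^-1; the default
#' 8-fold zero padding interpolates peak positions on a ~6 cm^-1 grid
#' (interpolation, not true resolution).
#'
#' @param residual Tibble `delay`, `residual` (uniform dense range; at least
#'   16 points after exclusion of long delays).
#' @param window_fn `"hann"` or `"rect"`.
#' @param pad_factor Zero-padding factor (default 8).
#' @param bin_width Resampling step in fs (default 18).
#' @param band_cm1 Analysis band (default 50-900 cm^-1).
#' @return A `trxps_oscspec` tibble `wavenumber`, `amplitude` with
#'   attributes `peaks` (tibble `wavenumber`, `amplitude`), `bin_cm1`
#'   (zero-padded bin width), `nyquist_cm1`.
#' @export
oscillation_spectrum <- function(residual, window_fn = c("hann", "rect"),
                                 pad_factor = 8, bin_width = 18,
                                 band_cm1 = c(50, 900)) {
  window_fn <- match.arg(window_fn)
  keep <- residual$delay < 1000
  res <- residual[keep, ]
  if (nrow(res) < 16) {
    abort("need at least 16 uniformly sampled points.",
          class = "trxps_analysis_error")
  }
  tg <- seq(min(res$delay), max(res$delay), by = bin_width)
  y <- approx(res$delay, res$residual, xout = tg)$y
  y <- y - mean(y)
  n <- length(y)
  w <- switch(window_fn,
              hann = 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))),
              rect = rep(1, n))
  yw <- y * w
  npad <- n * pad_factor
  yp <- c(yw, rep(0, npad - n))
  ft <- fft(yp)
  power_time <- sum(yw^2)
  power_freq <- sum(Mod(ft)^2) / npad
  amp <- Mod(ft)[seq_len(floor(npad / 2))]
  freq_hz <- (seq_along(amp) - 1) / (npad * bin_width * 1e-15)
  nu <- freq_hz / physical_constants$speed_of_light
  bin_cm1 <- nu[2] - nu[1]
  nyquist <- 1 / (2 * bin_width * 1e-15) / physical_constants$speed_of_light
  inband <- nu >= band_cm1[1] & nu <= band_cm1[2]
  # Rayleigh-distributed noise amplitudes stay below ~5x their median at
  # this record length; genuine coherent peaks sit an order of magnitude
  # above it
  floor_est <- 8 * median(amp[inband])
  is_peak <- inband &
    c(FALSE, diff(amp) > 0) & c(rev(diff(rev(amp)) > 0), FALSE) &
    amp > floor_est
  peaks <- tibble::tibble(wavenumber = nu[is_peak],
                          amplitude = amp[is_peak]) |>
    dplyr::arrange(dplyr::desc(.data$amplitude))
  out <- tibble::tibble(wavenumber = nu, amplitude = amp)
  structure(out, class = c("trxps_oscspec", class(out)),
            peaks = peaks, bin_cm1 = bin_cm1, nyquist_cm1 = nyquist,
            window = window_fn, pad_factor = pad_factor,
            power_time = power_time, power_freq = power_freq)
}

#' Extract the peak list of an oscillation spectrum
#'
#' @param spec A `trxps_oscspec`.
#' @return Tibble `wavenumber`, `amplitude`, strongest first.
#' @export
oscillation_peaks <- function(spec) attr(spec, "peaks")

#' Lag cross-correlation between an intensity trace and a bond series
#'
#' Normalized cross-correlation over a grid of lags (the bond series is
#' shifted by the lag before comparison); returns the lag maximizing the
#' absolute correlation and the signed coefficients, so antiphase
#' relationships appear as negative coefficients at zero lag.
#'
#' @param intensity Tibble `delay`, `value` (a detrended residual works
#'   best).
#' @param bonds Tibble `t`, `length` for a single bond (filter the output of
#'   [simulate_bond_series()]).
#' @param lag_range `c(lo, hi)` in fs.
#' @param lag_step Lag grid step (fs).
#' @return One-row tibble `best_lag`, `correlation`, `correlation_at_zero`
#'   with attribute `profile` (tibble `lag`, `correlation`).
#' @export
lag_correlation <- function(intensity, bonds, lag_range = c(-100, 100),
                            lag_step = NULL) {
  dt <- min(diff(sort(unique(intensity$delay))))
  lag_step <- lag_step %||% dt
  lags <- seq(lag_range[1], lag_range[2], by = lag_step)
  prof <- vapply(lags, function(L) {
    b <- approx(bonds$t + L, bonds$length, xout = intensity$delay)$y
    ok <- is.finite(b)
    if (sum(ok) < 8) return(NA_real_)
    x <- intensity$value[ok]; y <- b[ok]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (all(is.na(prof))) {
    abort("insufficient overlap between series over the lag range.",
          class = "trxps_analysis_error")
  }
  best <- which.max(abs(prof))
  zero_idx <- which.min(abs(lags))
  out <- tibble::tibble(best_lag = lags[best], correlation = prof[best],
                        correlation_at_zero = prof[zero_idx])
  attr(out, "profile") <- tibble::tibble(lag = lags, correlation = prof)
  out
}
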
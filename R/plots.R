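#' Plot a map pair as a difference map
#'
#' False-colour difference map (UV-on minus UV-off) over the dense delay
#' range: excited-state features positive, depletion negative.
#'
#' @param object A `trxps_map_pair`.
#' @param max_delay Upper delay limit shown (fs).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trxps_map_pair <- function(object, max_delay = 500, ...) {
  dm <- difference_map(object)
  dm <- dm[dm$delay <= max_delay, ]
  ggplot2::ggplot(dm, ggplot2::aes(x = .data$delay, y = .data$energy,
                                   fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "binding energy (eV)",
                  fill = "on - off") +
    ggplot2::theme_minimal()
}

#' Plot region-integrated time traces
#'
#' @param object A `trxps_traces` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by region.
#' @export
autoplot.trxps_traces <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delay, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$sigma,
                                          ymax = .data$value + .data$sigma),
                             size = 0.15) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "pump-probe delay (fs)",
                  y = "integrated difference counts") +
    ggplot2::theme_minimal()
}

#' Plot a global fit: data and fitted curves per region
#'
#' @param object A `trxps_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trxps_fit <- function(object, ...) {
  fd <- object$fitted
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$delay)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$value,
                                          ymin = .data$value - .data$sigma,
                                          ymax = .data$value + .data$sigma),
                             size = 0.15, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "integrated counts") +
    ggplot2::theme_minimal()
}

#' Plot an oscillation spectrum
#'
#' @param object A `trxps_oscspec`.
#' @param ... Unused.
#' @return A ggplot with detected peaks marked.
#' @export
autoplot.trxps_oscspec <- function(object, ...) {
  pk <- oscillation_peaks(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber,
                                            y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)),
                  y = "FFT amplitude") +
    ggplot2::theme_minimal()
  if (nrow(pk) > 0) {
    p <- p + ggplot2::geom_point(data = pk, colour = "red")
  }
  p
}

#' Plot a ground-state peak track
#'
#' @param object A `trxps_peaktrack`.
#' @param ... Unused.
#' @return A ggplot with the fitted mean and sigma width vs delay.
#' @export
autoplot.trxps_peaktrack <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[object$converged, c("delay", "mean", "sigma_width")],
    cols = c("mean", "sigma_width"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delay, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "eV") +
    ggplot2::theme_minimal()
}
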
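#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object A `uv_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uv_spectrum
#' @export
autoplot.uv_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a ratio or derivative trace
#'
#' Masked regions are left blank.
#'
#' @param object A `ratio_spectrum` or `deriv_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_spectrum
#' @export
autoplot.ratio_spectrum <- function(object, ...) {
  ylab <- if (inherits(object, "deriv_spectrum")) {
    "Derivative amplitude"
  } else "Ratio amplitude"
  ggplot2::ggplot(object[object$valid, ],
                  ggplot2::aes(.data$wavelength, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ratio_spectrum
#' @method autoplot deriv_spectrum
#' @export
autoplot.deriv_spectrum <- autoplot.ratio_spectrum

#' Plot a calibration line with its points
#'
#' @param object A `uv_calibration` fitted from data (fixed published
#'   calibrations have no stored points and cannot be plotted).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uv_calibration
#' @export
autoplot.uv_calibration <- function(object, ...) {
  if (is.null(object$data)) {
    rlang::abort("This calibration carries no data points to plot.")
  }
  ggplot2::ggplot(object$data, ggplot2::aes(.data$concentration, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "Concentration (ug/mL)", y = "Signal",
                  title = sprintf("%s calibration%s", toupper(object$method),
                                  if (is.null(object$analyte)) "" else
                                    paste0(" - ", object$analyte))) +
    ggplot2::theme_minimal()
}

#' Overlay several spectra
#'
#' @param spectra Named list of spectra on a common grid.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  if (is.null(names(spectra))) names(spectra) <- paste("spectrum", seq_along(spectra))
  df <- purrr::imap_dfr(spectra, function(s, nm) {
    tibble::tibble(wavelength = s$wavelength, absorbance = s$absorbance,
                   series = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$absorbance,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)", colour = NULL) +
    ggplot2::theme_minimal()
}
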
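#' Ordinary least-squares calibration line
#'
#' Fits signal on concentration by OLS and reports the quantities an
#' analytical calibration needs: slope, intercept, Pearson r, residual SD
#' (n - 2 denominator) and standard errors.
#'
#' @param x Concentrations (>= 3 distinct values).
#' @param y Signals, same length.
#' @return A `linear_fit` object.
#' @examples
#' fit_line(c(1, 2, 3), c(1, 2, 4)) # slope 1.5, intercept -0.5
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must match in length.")
  if (length(x) < 3) rlang::abort("At least 3 calibration points are required.")
  if (stats::var(x) == 0) rlang::abort("Concentrations must not all be equal.")
  fm <- stats::lm(y ~ x)
  # noise-free synthetic calibrations fit exactly; the perfect-fit warning
  # from summary.lm is expected there
  sm <- suppressWarnings(summary(fm))
  structure(
    list(
      slope = unname(stats::coef(fm)[["x"]]),
      intercept = unname(stats::coef(fm)[["(Intercept)"]]),
      r = stats::cor(x, y),
      residual_sd = sm$sigma,
      se_slope = sm$coefficients["x", "Std. Error"],
      se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
      n = length(x),
      data = tibble::tibble(concentration = x, signal = y)
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> signal = %.6g C %+.6g   r = %.5f, s(res) = %.4g, n = %d\n",
              x$slope, x$intercept, x$r, x$residual_sd, x$n))
  invisible(x)
}

new_calibration <- function(fit, method, analyte = NULL, wavelengths = NULL,
                            divisor = NULL, deriv = NULL, guard = 0.01) {
  cal <- fit
  cal$method <- method
  cal$analyte <- analyte
  cal$wavelengths <- wavelengths
  cal$divisor <- divisor
  cal$deriv <- deriv
  cal$guard <- guard
  class(cal) <- c("uv_calibration", "linear_fit")
  cal
}

#' Published regression equations as fixed calibrations
#'
#' The reported calibration lines for the aspirin/rivaroxaban binary mixture
#' (signal units: AU for dual wavelength, ratio-amplitude for ratio
#' difference, scaled derivative amplitude for derivative ratio; C in ug/mL):
#'
#' * ASP dual wavelength, dA(255.5, 242.5) = 0.0054 C + 0.001
#' * ROX dual wavelength, dA(286, 252) = 0.0291 C + 0.0003
#' * ASP ratio difference (divisor ROX 20 ug/mL), dP(234, 280) = 0.0221 C - 0.0099
#' * ROX ratio difference (divisor ASP 36 ug/mL), dP(254, 297) = 0.1444 C + 0.1495
#' * ASP derivative ratio (divisor ROX 20 ug/mL), P(238.5) = -0.0306 C + 0.0277
#' * ROX derivative ratio (divisor ASP 36 ug/mL), P(293) = 0.5056 C + 0.1667
#'
#' These are shipped reference constants for use as fixed calibrations (e.g.
#' inverting a measured signal to a concentration); the package never
#' recomputes them.
#'
#' @return Tibble with one row per analyte/method.
#' @export
published_calibrations <- function() {
  tibble::tribble(
    ~analyte, ~method, ~slope, ~intercept, ~r, ~wavelengths, ~divisor_label, ~divisor_concentration,
    "ASP", "dw", 0.0054, 0.001, 0.9998, c(242.5, 255.5), NA_character_, NA_real_,
    "ROX", "dw", 0.0291, 0.0003, 0.9997, c(252, 286), NA_character_, NA_real_,
    "ASP", "rd", 0.0221, -0.0099, 0.9998, c(234, 280), "ROX", 20,
    "ROX", "rd", 0.1444, 0.1495, 0.9999, c(254, 297), "ASP", 36,
    "ASP", "dd", -0.0306, 0.0277, 0.9999, 238.5, "ROX", 20,
    "ROX", "dd", 0.5056, 0.1667, 0.9999, 293, "ASP", 36
  )
}

#' Load a published regression as a fixed calibration object
#'
#' @param analyte `"ASP"` or `"ROX"`.
#' @param method `"dw"`, `"rd"` or `"dd"`.
#' @return A `uv_calibration` usable with [predict_concentration()] on
#'   numeric signals (it has no divisor spectrum attached, so it cannot score
#'   spectra directly).
#' @examples
#' cal <- fixed_calibration("ASP", "dw")
#' predict_concentration(cal, 0.109) # 20 ug/mL
#' @export
fixed_calibration <- function(analyte, method) {
  tbl <- published_calibrations()
  row <- tbl[tbl$analyte == analyte & tbl$method == method, ]
  if (nrow(row) != 1) rlang::abort("Unknown analyte/method combination.")
  fit <- structure(
    list(slope = row$slope, intercept = row$intercept, r = row$r,
         residual_sd = NA_real_, se_slope = NA_real_, se_intercept = NA_real_,
         n = NA_integer_, data = NULL),
    class = "linear_fit"
  )
  new_calibration(fit, method = method, analyte = analyte,
                  wavelengths = row$wavelengths[[1]])
}

#' Method signal of a sample under a calibration
#'
#' Computes the raw analytical signal a calibration is built on: the
#' absorbance difference A(high) - A(low) for dual wavelength, the
#' ratio-amplitude difference P(w1) - P(w2) for ratio difference, or the
#' derivative-ratio amplitude at the measurement wavelength for derivative
#' ratio. Ratio-based calibrations must carry their divisor spectrum.
#'
#' @param cal A `uv_calibration`.
#' @param sample A spectrum.
#' @return Numeric signal.
#' @export
signal_for <- function(cal, sample) {
  switch(
    cal$method,
    dw = delta_a(sample, cal$wavelengths),
    rd = {
      if (is.null(cal$divisor)) rlang::abort("Calibration has no divisor spectrum.")
      rd_signal(sample, cal$divisor, cal$wavelengths, guard = cal$guard)
    },
    dd = {
      if (is.null(cal$divisor)) rlang::abort("Calibration has no divisor spectrum.")
      dd_signal(sample, cal$divisor, cal$wavelengths,
                config = cal$deriv %||% deriv_config(), guard = cal$guard)
    },
    rlang::abort(sprintf("Unknown method '%s'.", cal$method))
  )
}

#' Invert a calibration to a concentration
#'
#' `C = (signal - intercept) / slope`. `sample` may be a numeric signal (or
#' vector of signals) or a spectrum, in which case the method signal is
#' computed first via [signal_for()].
#'
#' @param cal A `uv_calibration` or `linear_fit`.
#' @param sample Numeric signal(s) or a spectrum.
#' @return Concentration(s) in ug/mL.
#' @export
predict_concentration <- function(cal, sample) {
  if (is.null(cal$slope) || cal$slope == 0) rlang::abort("Calibration slope is zero.")
  sig <- if (is.numeric(sample)) sample else signal_for(cal, sample)
  (sig - cal$intercept) / cal$slope
}

#' @export
print.uv_calibration <- function(x, ...) {
  wl <- paste(format(x$wavelengths, trim = TRUE), collapse = ", ")
  cat(sprintf("<uv_calibration> %s%s @ %s nm\n",
              toupper(x$method),
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"), wl))
  if (!is.null(x$divisor)) {
    cat(sprintf("  divisor: %s %g ug/mL\n",
                attr(x$divisor, "label") %||% "?",
                attr(x$divisor, "concentration") %||% NA))
  }
  cat(sprintf("  signal = %.6g C %+.6g   r = %.5f, n = %s\n",
              x$slope, x$intercept, x$r, format(x$n)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration line
#'
#' @param x A `linear_fit` or `uv_calibration`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`.
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' One-row calibration summary
#'
#' @param x A `linear_fit` or `uv_calibration`.
#' @param ... Unused.
#' @return One-row tibble: slope, intercept, r, residual SD, n and, for
#'   method calibrations, method/analyte/wavelength metadata.
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  out <- tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                        residual_sd = x$residual_sd, n = x$n)
  if (inherits(x, "uv_calibration")) {
    out <- dplyr::mutate(
      out,
      method = x$method,
      analyte = x$analyte %||% NA_character_,
      wavelengths = paste(format(x$wavelengths, trim = TRUE), collapse = "/"),
      divisor = if (is.null(x$divisor)) NA_character_ else {
        sprintf("%s %g ug/mL", attr(x$divisor, "label") %||% "?",
                attr(x$divisor, "concentration") %||% NA)
      },
      .before = 1
    )
  }
  out
}
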
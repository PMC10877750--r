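#' Wavelength pair
#'
#' Orders and validates a dual-wavelength pair. Wavelengths may fall between
#' grid nodes (instrument software reports half-step positions such as
#' 242.5 nm on a 0.2 nm grid); readings there are linearly interpolated.
#'
#' @param lambda_low,lambda_high Wavelengths in nm, `lambda_low < lambda_high`.
#' @return Named numeric vector `c(low, high)`.
#' @export
wavelength_pair <- function(lambda_low, lambda_high) {
  if (!is.finite(lambda_low) || !is.finite(lambda_high)) {
    rlang::abort("Pair wavelengths must be finite.")
  }
  if (lambda_low >= lambda_high) rlang::abort("`lambda_low` must be < `lambda_high`.")
  c(low = lambda_low, high = lambda_high)
}

#' Dual-wavelength absorbance difference
#'
#' `dA = A(high) - A(low)` on the zero-order spectrum. At a pair where the
#' interferent absorbs equally, its contribution cancels and dA is directly
#' proportional to the analyte concentration.
#'
#' @param s A spectrum.
#' @param pair Length-2 numeric (low, high), see [wavelength_pair()].
#' @return Absorbance difference in AU.
#' @examples
#' # a flat spectrum gives 0 at any pair
#' @export
delta_a <- function(s, pair) {
  pair <- sort(as.numeric(pair))
  value_at(s, pair[[2]]) - value_at(s, pair[[1]])
}

#' Search for dual-wavelength pairs
#'
#' Exhaustive search over grid points in `window` for pairs where the
#' interferent's absorbance difference (at its top calibration level) is at
#' most `interferent_tolerance`, ranked by the analyte's absorbance
#' difference magnitude (at its top level), descending. Ties are broken by
#' smaller interferent difference, then lower `lambda_low`. With
#' `refine = TRUE` (default) the leading pairs are polished off-grid: one
#' wavelength is moved within one grid step (linear interpolation) to drive
#' the interferent difference to zero, removing the grid-quantization bias
#' that otherwise leaks the interferent into the prediction.
#'
#' @param analyte_set Calibration tibble (`concentration`, `spectrum`) of the
#'   analyte; the top level supplies the analyte signal.
#' @param interferent_top Spectrum of the interferent at its top calibration
#'   level.
#' @param interferent_tolerance Max |dA| of the interferent (AU) for a pair
#'   to qualify.
#' @param min_analyte_signal Min |dA| of the analyte (AU).
#' @param window Search window in nm.
#' @param min_separation Minimum pair separation in nm.
#' @param refine Polish leading pairs off-grid (see above).
#' @param max_pairs Number of ranked pairs to return.
#' @return Tibble `lambda_low`, `lambda_high`, `analyte_delta`,
#'   `interferent_delta`, best first; zero rows if no pair qualifies.
#' @export
select_pair <- function(analyte_set, interferent_top,
                        interferent_tolerance = 0.002,
                        min_analyte_signal = 0.01,
                        window = c(210, 340), min_separation = 2,
                        refine = TRUE, max_pairs = 20) {
  if (nrow(analyte_set) == 0) rlang::abort("Empty analyte calibration set.")
  if (interferent_tolerance <= 0) rlang::abort("`interferent_tolerance` must be > 0.")
  top <- analyte_set$spectrum[[which.max(analyte_set$concentration)]]
  if (!same_grid(top, interferent_top)) rlang::abort("Spectra are not on the same grid.")
  wl <- top$wavelength
  keep <- wl >= window[[1]] & wl <= window[[2]]
  wlw <- wl[keep]
  a <- top$absorbance[keep]
  i <- interferent_top$absorbance[keep]
  dI <- outer(i, i, `-`)   # dI[r, c] = I(c) - I(r) ... transpose care below
  dA <- outer(a, a, `-`)
  # entry [r, c] with c > r corresponds to pair (low = wlw[r], high = wlw[c]),
  # signal = x[c] - x[r] = -outer(x, x, `-`)[r, c]
  dI <- -dI
  dA <- -dA
  sep <- outer(wlw, wlw, function(p, q) q - p)
  ok <- upper.tri(dI) & sep >= min_separation &
    abs(dI) <= interferent_tolerance & abs(dA) >= min_analyte_signal
  if (!any(ok)) {
    return(tibble::tibble(lambda_low = numeric(), lambda_high = numeric(),
                          analyte_delta = numeric(), interferent_delta = numeric()))
  }
  idx <- which(ok, arr.ind = TRUE)
  res <- tibble::tibble(
    lambda_low = wlw[idx[, 1]],
    lambda_high = wlw[idx[, 2]],
    analyte_delta = dA[ok],
    interferent_delta = dI[ok]
  )
  res <- dplyr::arrange(res, dplyr::desc(abs(.data$analyte_delta)),
                        abs(.data$interferent_delta), .data$lambda_low)
  res <- utils::head(res, max_pairs)
  if (refine) {
    step <- grid_step(wl)
    res <- purrr::pmap_dfr(res, function(lambda_low, lambda_high, ...) {
      refine_pair(top, interferent_top, lambda_low, lambda_high, step,
                  window, min_separation)
    })
    res <- dplyr::arrange(res, dplyr::desc(abs(.data$analyte_delta)),
                          abs(.data$interferent_delta), .data$lambda_low)
  }
  res
}

# Move one wavelength of the pair within +/- one grid step so the
# interpolated interferent difference crosses zero; keep the grid pair if no
# sign change brackets a root.
refine_pair <- function(analyte_top, interferent_top, lo, hi, step,
                        window, min_separation) {
  f_lo <- function(x) value_at(interferent_top, x) - value_at(interferent_top, hi)
  try_root <- function(f, center, lower_lim, upper_lim) {
    lwr <- max(center - step, lower_lim)
    upr <- min(center + step, upper_lim)
    if (lwr >= upr) return(NULL)
    fl <- f(lwr); fu <- f(upr)
    if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) return(NULL)
    stats::uniroot(f, c(lwr, upr), tol = 1e-12)$root
  }
  new_lo <- try_root(f_lo, lo, window[[1]], hi - min_separation)
  if (!is.null(new_lo)) {
    lo <- new_lo
  } else {
    g <- function(x) value_at(interferent_top, x) - value_at(interferent_top, lo)
    new_hi <- try_root(g, hi, lo + min_separation, window[[2]])
    if (!is.null(new_hi)) hi <- new_hi
  }
  tibble::tibble(
    lambda_low = lo, lambda_high = hi,
    analyte_delta = delta_a(analyte_top, c(lo, hi)),
    interferent_delta = delta_a(interferent_top, c(lo, hi))
  )
}

#' Calibrate the dual-wavelength method
#'
#' Regresses the absorbance difference at `pair` on concentration over a
#' calibration set (>= 3 distinct levels).
#'
#' @param standards Calibration tibble (`concentration`, `spectrum`).
#' @param pair Wavelength pair (low, high).
#' @param analyte Optional analyte label stored on the calibration.
#' @return A `uv_calibration` (method `"dw"`).
#' @export
dw_calibrate <- function(standards, pair, analyte = NULL) {
  pair <- sort(as.numeric(pair))
  sig <- purrr::map_dbl(standards$spectrum, delta_a, pair = pair)
  fit <- fit_line(standards$concentration, sig)
  new_calibration(fit, method = "dw", analyte = analyte, wavelengths = pair)
}

#' Predict a concentration by dual wavelength
#'
#' @param sample A spectrum (or numeric dA signal).
#' @param cal A dual-wavelength `uv_calibration`.
#' @return Concentration in ug/mL.
#' @examples
#' predict_concentration(fixed_calibration("ROX", "dw"), 0.0294) # 1 ug/mL
#' @export
dw_predict <- function(sample, cal) {
  if (!identical(cal$method, "dw")) rlang::abort("Not a dual-wavelength calibration.")
  predict_concentration(cal, sample)
}
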
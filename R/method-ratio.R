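#' Make a divisor spectrum
#'
#' A divisor is a standard spectrum of one component at a stated
#' concentration, used as the denominator of ratio spectra. Any spectrum with
#' `label` and `concentration` attributes works; this helper builds one from
#' a component model.
#'
#' @param model A [component_model()].
#' @param concentration Divisor concentration in ug/mL (> 0).
#' @param grid Wavelength grid.
#' @return A spectrum.
#' @export
make_divisor <- function(model, concentration, grid = scan_grid()) {
  if (concentration <= 0) rlang::abort("Divisor concentration must be > 0.")
  b <- basis_spectrum(model, grid)
  new_spectrum(grid, concentration * b$absorbance,
               label = attr(model, "label"), concentration = concentration)
}

#' Ratio-difference signal
#'
#' Amplitude difference of the ratio spectrum at an ordered wavelength pair:
#' `dP = P(w1) - P(w2)`. The divisor's own component contributes a constant
#' to the ratio spectrum, so it cancels in the difference; the pair order is
#' part of the method configuration (chosen so the calibration slope is
#' positive) and is preserved as given.
#'
#' @param sample A spectrum.
#' @param divisor Divisor spectrum (same grid).
#' @param pair Length-2 numeric `(w1, w2)`, order preserved.
#' @param guard Divisor guard threshold (AU), see [ratio_spectrum()].
#' @return Amplitude difference (dimensionless).
#' @export
rd_signal <- function(sample, divisor, pair, guard = 0.01) {
  rs <- ratio_spectrum(sample, divisor, guard = guard)
  value_at(rs, pair[[1]]) - value_at(rs, pair[[2]])
}

#' Choose a ratio-difference wavelength pair
#'
#' Picks the pair maximizing the analyte's ratio-amplitude difference: the
#' argmax and argmin of the top standard's ratio trace over the valid region
#' (optionally restricted to `window`), ordered so the resulting calibration
#' slope is positive.
#'
#' @param standards Calibration tibble of the analyte.
#' @param divisor Divisor spectrum.
#' @param window Optional nm range to restrict the search.
#' @param guard Divisor guard threshold (AU).
#' @param edge_margin Points this close (nm) to a mask/grid edge are skipped,
#'   so the pair stays usable after derivative-style windowing too.
#' @return Numeric pair `(w1, w2)` in signal order.
#' @export
rd_select_pair <- function(standards, divisor, window = NULL, guard = 0.01,
                           edge_margin = 2) {
  top <- standards$spectrum[[which.max(standards$concentration)]]
  rs <- ratio_spectrum(top, divisor, guard = guard)
  ok <- rs$valid
  if (!is.null(window)) ok <- ok & rs$wavelength >= window[[1]] & rs$wavelength <= window[[2]]
  # stay clear of mask edges
  margin_pts <- ceiling(edge_margin / grid_step(rs$wavelength))
  inner <- ok
  for (k in seq_len(margin_pts)) {
    inner <- inner & dplyr::lag(ok, k, default = FALSE) &
      dplyr::lead(ok, k, default = FALSE)
  }
  if (!any(inner)) rlang::abort("No valid interior region for pair selection.")
  amp <- ifelse(inner, rs$amplitude, NA_real_)
  w_max <- rs$wavelength[[which.max(amp)]]
  w_min <- rs$wavelength[[which.min(amp)]]
  c(w_max, w_min) # P(max) - P(min) > 0 for positive analyte => positive slope
}

#' Calibrate the ratio-difference method
#'
#' Regresses dP at `pair` on concentration. With `orient = "positive_slope"`
#' (default) the pair order is flipped if the fitted slope is negative, so
#' the stored configuration is unambiguous about sign.
#'
#' @param standards Calibration tibble (`concentration`, `spectrum`).
#' @param divisor Divisor spectrum.
#' @param pair Wavelength pair `(w1, w2)`.
#' @param guard Divisor guard threshold (AU).
#' @param orient `"positive_slope"` or `"as_given"`.
#' @param analyte Optional analyte label.
#' @return A `uv_calibration` (method `"rd"`) carrying the divisor spectrum.
#' @export
rd_calibrate <- function(standards, divisor, pair, guard = 0.01,
                         orient = c("positive_slope", "as_given"),
                         analyte = NULL) {
  orient <- rlang::arg_match(orient)
  sig <- purrr::map_dbl(standards$spectrum, rd_signal, divisor = divisor,
                        pair = pair, guard = guard)
  fit <- fit_line(standards$concentration, sig)
  if (orient == "positive_slope" && fit$slope < 0) {
    pair <- rev(pair)
    fit <- fit_line(standards$concentration, -sig)
  }
  new_calibration(fit, method = "rd", analyte = analyte, wavelengths = pair,
                  divisor = divisor, guard = guard)
}

#' Predict a concentration by ratio difference
#'
#' @param sample A spectrum (or numeric dP signal).
#' @param cal A ratio-difference `uv_calibration`.
#' @return Concentration in ug/mL.
#' @examples
#' predict_concentration(fixed_calibration("ROX", "rd"), 1.5935) # 10 ug/mL
#' @export
rd_predict <- function(sample, cal) {
  if (!identical(cal$method, "rd")) rlang::abort("Not a ratio-difference calibration.")
  predict_concentration(cal, sample)
}

#' Derivative-ratio signal
#'
#' First derivative of the ratio spectrum, read at the measurement
#' wavelength. The divisor-matched component's constant contribution
#' differentiates to exactly zero.
#'
#' @param sample A spectrum.
#' @param divisor Divisor spectrum.
#' @param wavelength Measurement wavelength (nm), interior to the valid
#'   region after windowing.
#' @param config A [deriv_config()].
#' @param guard Divisor guard threshold (AU).
#' @return Scaled derivative amplitude.
#' @export
dd_signal <- function(sample, divisor, wavelength, config = deriv_config(),
                      guard = 0.01) {
  rs <- ratio_spectrum(sample, divisor, guard = guard)
  dv <- derivative_spectrum(rs, config)
  value_at(dv, wavelength)
}

#' Calibrate the derivative-ratio method
#'
#' @inheritParams dd_signal
#' @param standards Calibration tibble (`concentration`, `spectrum`).
#' @param analyte Optional analyte label.
#' @return A `uv_calibration` (method `"dd"`).
#' @export
dd_calibrate <- function(standards, divisor, wavelength,
                         config = deriv_config(), guard = 0.01,
                         analyte = NULL) {
  sig <- purrr::map_dbl(standards$spectrum, dd_signal, divisor = divisor,
                        wavelength = wavelength, config = config, guard = guard)
  fit <- fit_line(standards$concentration, sig)
  new_calibration(fit, method = "dd", analyte = analyte,
                  wavelengths = wavelength, divisor = divisor,
                  deriv = config, guard = guard)
}

#' Predict a concentration by derivative ratio
#'
#' @param sample A spectrum (or numeric P signal).
#' @param cal A derivative-ratio `uv_calibration`.
#' @return Concentration in ug/mL.
#' @examples
#' predict_concentration(fixed_calibration("ROX", "dd"), 5.2227) # 10 ug/mL
#' @export
dd_predict <- function(sample, cal) {
  if (!identical(cal$method, "dd")) rlang::abort("Not a derivative-ratio calibration.")
  predict_concentration(cal, sample)
}

#' Candidate measurement wavelengths for the derivative-ratio method
#'
#' Locates the peaks and troughs of the mean derivative-ratio trace of the
#' standards (sign change of the discrete first difference, minimum
#' prominence to suppress noise wiggles), regresses the per-wavelength signal
#' on concentration at each, and ranks the qualifying candidates
#' (`r >= r_min`) by sensitivity (absolute slope), descending.
#'
#' @inheritParams dd_calibrate
#' @param r_min Minimum absolute correlation for a candidate to qualify.
#' @param prominence Minimum extremum prominence on the mean trace.
#' @return Tibble `wavelength`, `slope`, `r`, `qualifies`, qualifying
#'   candidates first, by |slope| descending; zero rows if no extrema.
#' @export
dd_candidate_wavelengths <- function(standards, divisor,
                                     config = deriv_config(), guard = 0.01,
                                     r_min = 0.999, prominence = 1e-4) {
  if (nrow(standards) < 3) rlang::abort("Need >= 3 calibration levels.")
  traces <- purrr::map(standards$spectrum, function(s) {
    derivative_spectrum(ratio_spectrum(s, divisor, guard = guard), config)
  })
  amp <- purrr::map(traces, "amplitude")
  valid <- purrr::reduce(purrr::map(traces, "valid"), `&`)
  mean_trace <- purrr::reduce(amp, `+`) / length(amp)
  wl <- traces[[1]]$wavelength
  ext <- find_extrema(wl, mean_trace, valid, prominence)
  if (length(ext) == 0) {
    return(tibble::tibble(wavelength = numeric(), slope = numeric(),
                          r = numeric(), qualifies = logical()))
  }
  rows <- purrr::map_dfr(ext, function(i) {
    sig <- purrr::map_dbl(amp, ~ .x[[i]])
    fit <- fit_line(standards$concentration, sig)
    tibble::tibble(wavelength = wl[[i]], slope = fit$slope, r = fit$r)
  })
  rows$qualifies <- abs(rows$r) >= r_min
  dplyr::arrange(rows, dplyr::desc(.data$qualifies), dplyr::desc(abs(.data$slope)))
}

# Interior extrema of y over valid runs: sign change of diff(y), with
# prominence = min height difference to the neighbouring opposite extrema
# (range endpoints counting as extrema).
find_extrema <- function(wl, y, valid, prominence) {
  n <- length(y)
  cand <- integer()
  for (i in 2:(n - 1)) {
    if (!valid[i - 1] || !valid[i] || !valid[i + 1]) next
    d1 <- y[i] - y[i - 1]
    d2 <- y[i + 1] - y[i]
    if (d1 == 0) next
    if (sign(d1) != sign(d2) && d2 != 0) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(integer())
  keep <- vapply(seq_along(cand), function(k) {
    i <- cand[[k]]
    left <- if (k == 1) {
      run_start <- i
      while (run_start > 1 && valid[run_start - 1]) run_start <- run_start - 1
      y[run_start]
    } else y[cand[[k - 1]]]
    right <- if (k == length(cand)) {
      run_end <- i
      while (run_end < length(y) && valid[run_end + 1]) run_end <- run_end + 1
      y[run_end]
    } else y[cand[[k + 1]]]
    min(abs(y[i] - left), abs(y[i] - right)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Choose the best divisor for a ratio method
#'
#' Scores each candidate divisor by leave-one-out recovery RSD over the
#' calibration standards (for each standard: calibrate on the others,
#' predict it, express as recovery %), with calibration r as a secondary
#' diagnostic. Returns the candidate minimizing the LOO RSD; ties are broken
#' by higher sensitivity (|slope|), then input order. Candidates whose
#' calibration fails (e.g. masked measurement region) are marked and skipped.
#'
#' @param standards Calibration tibble of the analyte.
#' @param candidates List of divisor spectra (>= 2).
#' @param method `"rd"` or `"dd"`.
#' @param pair For `"rd"`: wavelength pair, or `NULL` to auto-select per
#'   candidate via [rd_select_pair()].
#' @param wavelength For `"dd"`: measurement wavelength, or `NULL` to take
#'   each candidate's top-ranked [dd_candidate_wavelengths()] result.
#' @param config Derivative configuration for `"dd"`.
#' @param guard Divisor guard threshold (AU).
#' @return List with `best` (divisor spectrum), `best_index`, and
#'   `diagnostics` (tibble: label, concentration, slope, r, loo_rsd, ok).
#' @export
optimize_divisor <- function(standards, candidates, method = c("rd", "dd"),
                             pair = NULL, wavelength = NULL,
                             config = deriv_config(), guard = 0.01) {
  method <- rlang::arg_match(method)
  if (length(candidates) < 2) rlang::abort("Need >= 2 divisor candidates.")
  diag <- purrr::imap_dfr(candidates, function(div, k) {
    res <- tryCatch({
      if (method == "rd") {
        p <- pair %||% rd_select_pair(standards, div, guard = guard)
        calib <- function(std) rd_calibrate(std, div, p, guard = guard,
                                            orient = "as_given")
      } else {
        w <- wavelength %||% {
          cands <- dd_candidate_wavelengths(standards, div, config = config,
                                            guard = guard)
          if (nrow(cands) == 0 || !any(cands$qualifies)) {
            rlang::abort("No qualifying derivative extremum.")
          }
          cands$wavelength[[1]]
        }
        calib <- function(std) dd_calibrate(std, div, w, config = config,
                                            guard = guard)
      }
      full <- calib(standards)
      rec <- purrr::map_dbl(seq_len(nrow(standards)), function(i) {
        cal_i <- calib(standards[-i, ])
        found <- predict_concentration(cal_i, standards$spectrum[[i]])
        recovery_percent(found, standards$concentration[[i]])
      })
      list(slope = full$slope, r = full$r, loo_rsd = precision_rsd(rec), ok = TRUE)
    }, error = function(e) list(slope = NA_real_, r = NA_real_,
                                loo_rsd = NA_real_, ok = FALSE))
    tibble::tibble(
      index = k,
      label = attr(div, "label") %||% NA_character_,
      concentration = attr(div, "concentration") %||% NA_real_,
      slope = res$slope, r = res$r, loo_rsd = res$loo_rsd, ok = res$ok
    )
  })
  usable <- dplyr::filter(diag, .data$ok)
  if (nrow(usable) == 0) rlang::abort("All divisor candidates failed calibration.")
  # tie tolerance on RSD: numerically indistinguishable RSDs fall to |slope|
  best_rsd <- min(usable$loo_rsd)
  tied <- dplyr::filter(usable, .data$loo_rsd <= best_rsd + 1e-9)
  tied <- dplyr::arrange(tied, dplyr::desc(abs(.data$slope)), .data$index)
  best_index <- tied$index[[1]]
  list(best = candidates[[best_index]], best_index = best_index,
       diagnostics = diag)
}
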
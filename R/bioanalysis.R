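#' Dilution-chain arithmetic
#'
#' Final concentration after an ordered series of dilution steps, each taking
#' an aliquot into a final (total) volume:
#' `final = initial * prod(aliquot / total)`. Volume-neutral handling steps
#' (vortexing, centrifugation, filtration) do not appear in the chain.
#'
#' @param steps Data frame with columns `aliquot` and `total` (mL); every
#'   aliquot must be positive and no larger than its step's total volume.
#' @param initial_concentration Starting concentration, ug/mL.
#' @return Final concentration, ug/mL.
#' @examples
#' # plasma protocol: 4 mL spike into 0.5 mL plasma + 0.5 mL methanol (5 mL),
#' # then 2 mL of filtrate into a 10 mL flask
#' final_concentration(plasma_protocol_steps(), 25) # 4 ug/mL
#' @export
final_concentration <- function(steps, initial_concentration) {
  if (!all(c("aliquot", "total") %in% names(steps))) {
    rlang::abort("`steps` needs columns `aliquot` and `total`.")
  }
  if (any(steps$aliquot <= 0) || any(steps$total <= 0)) {
    rlang::abort("Volumes must be > 0.")
  }
  if (any(steps$aliquot > steps$total)) {
    rlang::abort("Each aliquot must be <= its step's total volume.")
  }
  # products taken separately so protocol chains with exact decimal volumes
  # reproduce their printed finals exactly
  initial_concentration * prod(steps$aliquot) / prod(steps$total)
}

#' Plasma deproteination dilution steps
#'
#' The two-step chain of the spiked-plasma protocol: 4 mL of spiking mixture
#' added to 0.5 mL plasma plus 0.5 mL methanol precipitant (5 mL total, of
#' which the spike's 4 mL carries the analyte), then 2 mL of the filtrate
#' diluted to 10 mL. The 5 mL intermediate volume is the only arithmetic
#' consistent with the protocol's final concentrations (e.g. a 25 ug/mL
#' spiking mixture ends at 4 ug/mL).
#'
#' @return Tibble of `aliquot`/`total` volumes (mL).
#' @export
plasma_protocol_steps <- function() {
  tibble::tibble(aliquot = c(4, 2), total = c(5, 10))
}

#' Matrix interference check
#'
#' Computes each supplied method's analytical signal on a blank-matrix
#' spectrum and on the top calibration standard, and flags interference when
#' the |blank| / |top standard| signal ratio exceeds `threshold` at any
#' configured wavelength.
#'
#' @param blank Blank matrix spectrum (e.g. deproteinated blank plasma).
#' @param top_standard Spectrum of the top calibration standard on the same
#'   grid.
#' @param calibrations List of `uv_calibration` objects whose method signals
#'   (dA, dP or P) define the checks.
#' @param threshold Maximum tolerated |blank| / |top| ratio (default 0.02).
#' @return Tibble: `method`, `wavelengths`, `blank_signal`, `top_signal`,
#'   `ratio`, `pass`; attribute `"pass"` gives the overall verdict.
#' @export
interference_check <- function(blank, top_standard, calibrations,
                               threshold = 0.02) {
  if (!same_grid(blank, top_standard)) {
    rlang::abort("Blank and standard are not on the same grid.")
  }
  rows <- purrr::map_dfr(calibrations, function(cal) {
    b <- signal_for(cal, blank)
    s <- signal_for(cal, top_standard)
    if (s == 0) rlang::abort("Top standard signal is zero.")
    tibble::tibble(
      method = cal$method,
      wavelengths = paste(format(cal$wavelengths, trim = TRUE), collapse = "/"),
      blank_signal = b, top_signal = s,
      ratio = abs(b) / abs(s),
      pass = abs(b) / abs(s) <= threshold
    )
  })
  attr(rows, "pass") <- all(rows$pass)
  rows
}
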
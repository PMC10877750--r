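# Shared builders for the synthetic two-component system used across tests.

test_models <- default_models()
test_grid <- scan_grid()

test_standards <- function(component,
                           levels = if (component == "asp") {
                             c(4, 8, 16, 24, 32, 40)
                           } else c(2, 4, 8, 12, 16, 20),
                           ...) {
  make_calibration_set(test_models, component, levels, grid = test_grid, ...)
}

test_divisor <- function(of = c("asp", "rox"),
                         concentration = if (of == "asp") 20 else 36) {
  of <- match.arg(of)
  # divisor for analyte `of` is a standard of the OTHER component
  other <- setdiff(c("asp", "rox"), of)
  make_divisor(test_models[[other]], concentration, test_grid)
}

# Calibrate all three methods for both analytes on noise-free standards,
# auto-selecting wavelengths. Memoised: built once per test run.
test_calibrations <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    std <- list(asp = test_standards("asp"), rox = test_standards("rox"))
    div <- list(asp = test_divisor("asp"), rox = test_divisor("rox"))
    cals <- list()
    for (an in c("asp", "rox")) {
      other <- setdiff(c("asp", "rox"), an)
      top_other <- std[[other]]$spectrum[[nrow(std[[other]])]]
      pairs <- select_pair(std[[an]], top_other)
      cals[[paste0(an, "_dw")]] <-
        dw_calibrate(std[[an]], c(pairs$lambda_low[[1]], pairs$lambda_high[[1]]),
                     analyte = an)
      rp <- rd_select_pair(std[[an]], div[[an]])
      cals[[paste0(an, "_rd")]] <- rd_calibrate(std[[an]], div[[an]], rp,
                                                analyte = an)
      cands <- dd_candidate_wavelengths(std[[an]], div[[an]])
      cals[[paste0(an, "_dd")]] <-
        dd_calibrate(std[[an]], div[[an]], cands$wavelength[[1]], analyte = an)
    }
    cache <<- cals
    cals
  }
})

# Analytic derivative of a component model's basis spectrum at wavelength w.
basis_deriv_analytic <- function(model, w) {
  sum(purrr::pmap_dbl(model, function(center, width, height) {
    height * exp(-(w - center)^2 / (2 * width^2)) * (center - w) / width^2
  }))
}

basis_value_analytic <- function(model, w) {
  sum(purrr::pmap_dbl(model, function(center, width, height) {
    height * exp(-(w - center)^2 / (2 * width^2))
  }))
}
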
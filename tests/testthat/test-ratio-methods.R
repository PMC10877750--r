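test_that("rd and dd signals cancel any divisor-component contribution", {
  div <- test_divisor("asp") # ROX-like standard at 20 ug/mL
  pair <- rd_select_pair(test_standards("asp"), div)
  base <- make_mixture(test_models, c(asp = 12))
  s0_rd <- rd_signal(base, div, pair)
  dd_w <- 250
  s0_dd <- dd_signal(base, div, dd_w)
  for (k in c(0.5, 2, 5, 20)) {
    spiked <- make_mixture(test_models, c(asp = 12, rox = k))
    expect_lt(abs(rd_signal(spiked, div, pair) - s0_rd), 1e-9)
    expect_lt(abs(dd_signal(spiked, div, dd_w) - s0_dd), 1e-9)
  }
  # a sample proportional to the divisor has a flat ratio: dP = 0, P = 0
  prop <- make_mixture(test_models, c(rox = 7))
  expect_equal(rd_signal(prop, div, pair), 0, tolerance = 1e-12)
  expect_equal(dd_signal(prop, div, dd_w), 0, tolerance = 1e-12)
})

test_that("published ratio fits invert to the derived concentrations", {
  expect_equal(rd_predict(1.5935, fixed_calibration("ROX", "rd")), 10,
               tolerance = 1e-9)
  asp_rd <- fixed_calibration("ASP", "rd")
  expect_equal(asp_rd$slope, 0.0221)
  expect_equal(asp_rd$intercept, -0.0099)
  expect_equal(rd_predict(0.0221 * 14 - 0.0099, asp_rd), 14, tolerance = 1e-9)
  expect_equal(dd_predict(-0.2783, fixed_calibration("ASP", "dd")), 10,
               tolerance = 1e-9)
  expect_equal(dd_predict(5.2227, fixed_calibration("ROX", "dd")), 10,
               tolerance = 1e-9)
})

test_that("rd calibration is exact noise-free and slope scales as 1/divisor", {
  std <- test_standards("asp")
  div20 <- test_divisor("asp", concentration = 20)
  div40 <- test_divisor("asp", concentration = 40)
  pair <- rd_select_pair(std, div20)
  cal20 <- rd_calibrate(std, div20, pair, orient = "as_given")
  cal40 <- rd_calibrate(std, div40, pair, orient = "as_given")
  expect_equal(abs(cal20$r), 1, tolerance = 1e-12)
  expect_equal(cal40$slope, cal20$slope / 2, tolerance = 1e-10)
  # positive-slope orientation flips a reversed pair
  calrev <- rd_calibrate(std, div20, rev(pair))
  expect_gt(calrev$slope, 0)
  expect_equal(calrev$wavelengths, pair)
})

test_that("derivative-ratio signal converges to the analytic ratio derivative", {
  div <- test_divisor("asp")
  s <- make_mixture(test_models, c(asp = 10))
  num <- function(x) 10 * basis_value_analytic(test_models$asp, x)
  den <- function(x) 20 * basis_value_analytic(test_models$rox, x)
  num_d <- function(x) 10 * basis_deriv_analytic(test_models$asp, x)
  den_d <- function(x) 20 * basis_deriv_analytic(test_models$rox, x)
  for (w in c(240, 250, 260)) {
    analytic <- 10 * (num_d(w) * den(w) - num(w) * den_d(w)) / den(w)^2
    err4 <- abs(dd_signal(s, div, w, deriv_config(delta_lambda = 4)) - analytic)
    err2 <- abs(dd_signal(s, div, w, deriv_config(delta_lambda = 2)) - analytic)
    # within a couple of percent at the working window...
    expect_lt(err4, 0.02 * abs(analytic))
    # ...and second-order in the window width (halving shrinks error ~4x)
    expect_gt(err4 / err2, 2.5)
    expect_lt(err4 / err2, 6)
  }
})

test_that("dd candidate search finds the extrema and ranks by sensitivity", {
  # single Gaussian analyte over a flat divisor: exactly two extrema
  flat_model <- component_model("flat", 275, 1e5, 0.02)
  gauss_model <- component_model("peak", 260, 10, 0.03)
  models <- list(flat = flat_model, peak = gauss_model)
  std <- make_calibration_set(models, "peak", c(2, 6, 10), grid = test_grid)
  div <- make_divisor(flat_model, 1, test_grid)
  cands <- dd_candidate_wavelengths(std, div, prominence = 1e-3)
  expect_equal(nrow(cands), 2)
  # Gaussian derivative extrema sit at center +/- sigma
  expect_equal(sort(cands$wavelength), c(250, 270), tolerance = 0.5)
  expect_true(all(cands$qualifies))
  expect_gte(abs(cands$slope[[1]]), abs(cands$slope[[2]]))
  # analyte proportional to the divisor leaves no usable extrema
  std_prop <- make_calibration_set(models, "flat", c(2, 6, 10), grid = test_grid)
  cands2 <- dd_candidate_wavelengths(std_prop, div, prominence = 1e-3)
  expect_equal(nrow(cands2), 0)
  # ranking contract on the real system
  std_rox <- test_standards("rox")
  c3 <- dd_candidate_wavelengths(std_rox, test_divisor("rox"))
  qual <- c3[c3$qualifies, ]
  expect_equal(abs(qual$slope[[1]]), max(abs(qual$slope)))
})

test_that("divisor optimization prefers low-RSD, then high-sensitivity divisors", {
  std <- test_standards("asp")
  divs <- list(test_divisor("asp", 20), test_divisor("asp", 20))
  pick <- optimize_divisor(std, divs, method = "rd")
  expect_equal(pick$best_index, 1) # deterministic tie-break
  # noise-free: all RSD ~ 0, tie-break by |slope| picks the smallest divisor
  divs2 <- list(test_divisor("asp", 40), test_divisor("asp", 20),
                test_divisor("asp", 10))
  # evaluate all candidates at a pair valid for the weakest divisor, so
  # slopes scale cleanly as 1/divisor concentration
  pick2 <- optimize_divisor(std, divs2, method = "rd",
                            pair = rd_select_pair(std, divs2[[3]]))
  expect_equal(pick2$best_index, 3)
  expect_true(all(pick2$diagnostics$loo_rsd < 1e-6))
  # a divisor that is dark across the spectrum is rejected, not fatal
  dark <- new_spectrum(test_grid, rep(1e-4, 751), label = "dark",
                       concentration = 1)
  pick3 <- optimize_divisor(std, list(test_divisor("asp", 20), dark),
                            method = "dd")
  expect_equal(pick3$best_index, 1)
  expect_false(pick3$diagnostics$ok[[2]])
  expect_error(optimize_divisor(std, list(dark, dark), method = "rd"),
               "failed")
})

test_that("noise-free mixtures: all three methods agree with truth and each other", {
  cals <- test_calibrations()
  grid_conc <- tidyr::expand_grid(asp = c(4, 12, 20, 30, 40),
                                  rox = c(2, 6, 10, 15, 20))
  worst <- 0
  for (i in seq_len(nrow(grid_conc))) {
    s <- make_mixture(test_models, c(asp = grid_conc$asp[[i]],
                                     rox = grid_conc$rox[[i]]))
    for (an in c("asp", "rox")) {
      truth <- grid_conc[[an]][[i]]
      preds <- c(dw = predict_concentration(cals[[paste0(an, "_dw")]], s),
                 rd = predict_concentration(cals[[paste0(an, "_rd")]], s),
                 dd = predict_concentration(cals[[paste0(an, "_dd")]], s))
      worst <- max(worst, abs(100 * preds / truth - 100))
    }
  }
  expect_lt(worst, 0.5)
})
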
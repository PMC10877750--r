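test_that("CSV round trip reproduces absorbances and metadata columns", {
  s <- basis_spectrum(test_models$asp, test_grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(nrow(back), 751)
  expect_lt(max(abs(back$absorbance - s$absorbance)), 1e-9)
  expect_equal(back$wavelength, s$wavelength)
})

test_that("reading resamples coarser grids by linear interpolation", {
  wl <- seq(200, 350, by = 1)
  ab <- 0.002 * (wl - 200) # exact line: interpolation is exact on it
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(wavelength_nm = wl, absorbance = ab), path)
  s <- read_spectrum(path, grid = test_grid)
  expect_equal(nrow(s), 751)
  # hand interpolation at three off-node wavelengths
  for (w in c(210.4, 275.2, 349.8)) {
    expect_equal(value_at(s, w), 0.002 * (w - 200), tolerance = 1e-12)
  }
  # and on a curved trace, interpolation sits between the bracketing nodes
  ab2 <- exp(-(wl - 260)^2 / 800)
  readr::write_csv(tibble::tibble(w = wl, a = ab2), path)
  s2 <- read_spectrum(path, grid = test_grid)
  i <- which(wl == 260)
  expect_equal(value_at(s2, 260.5),
               ab2[[i]] + 0.5 * (ab2[[i + 1]] - ab2[[i]]), tolerance = 1e-12)
})

test_that("malformed spectrum files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), path)
  expect_error(read_spectrum(path), "Empty")
  writeLines(c("wavelength_nm,absorbance", "200,0.1", "200.2,abc"), path)
  expect_error(read_spectrum(path), "Non-numeric")
  writeLines(c("200,0.1", "200,0.2", "200.2,0.1"), path)
  expect_error(read_spectrum(path), "Duplicate")
  writeLines(c("190,0.1", paste(seq(200, 350, 0.2), "0.1", sep = ",")), path)
  expect_warning(s <- read_spectrum(path, grid = test_grid), "clipped")
  expect_equal(nrow(s), 751)
})

test_that("JCAMP-DX XYDATA blocks are read and match the CSV twin", {
  wl <- seq(230, 239, by = 1)
  ab <- round(exp(-(wl - 234)^2 / 8), 4)
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic check",
    "##JCAMP-DX=4.24",
    "##XUNITS=NANOMETERS", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.0001",
    "##FIRSTX=230", "##LASTX=239", "##NPOINTS=10",
    "##XYDATA=(X++(Y..Y))",
    paste(230, paste(ab[1:5] * 10000, collapse = " ")),
    paste(235, paste(ab[6:10] * 10000, collapse = " ")),
    "##END="
  ), path)
  s <- read_spectrum(path)
  expect_equal(s$wavelength, wl)
  expect_equal(s$absorbance, ab, tolerance = 1e-12)
})

test_that("subtraction is pointwise and demands a shared grid", {
  a <- basis_spectrum(test_models$rox, test_grid)
  expect_true(all(subtract_spectrum(a, a)$absorbance == 0))
  zero <- new_spectrum(test_grid, rep(0, 751))
  expect_equal(subtract_spectrum(a, zero)$absorbance, a$absorbance)
  b <- basis_spectrum(test_models$rox, scan_grid(200, 300))
  expect_error(subtract_spectrum(a, b), "grid")
  # mixture minus blank baseline recovers the analyte-only spectrum
  mix <- make_mixture(test_models, c(asp = 8), baseline = plasma_baseline_model())
  blank <- make_mixture(test_models, c(asp = 0), baseline = plasma_baseline_model())
  pure <- make_mixture(test_models, c(asp = 8))
  expect_lt(max(abs(subtract_spectrum(mix, blank)$absorbance - pure$absorbance)),
            1e-12)
})

test_that("ratio spectra divide pointwise, mask weak divisors, and invert", {
  s <- make_mixture(test_models, c(rox = 10))
  same <- ratio_spectrum(s, s, guard = 0.01)
  expect_true(all(abs(same$amplitude[same$valid] - 1) < 1e-12))
  half <- new_spectrum(test_grid, s$absorbance / 2, label = "half",
                       concentration = 5)
  doubled <- ratio_spectrum(s, half)
  expect_true(all(abs(doubled$amplitude[doubled$valid] - 2) < 1e-12))
  # masked where divisor < guard, and a fully-dark divisor errors
  div <- test_divisor("rox")
  rs <- ratio_spectrum(s, div)
  expect_true(any(!rs$valid))
  expect_true(all(is.na(rs$amplitude[!rs$valid])))
  dark <- new_spectrum(test_grid, rep(1e-4, 751))
  expect_error(ratio_spectrum(s, dark), "guard")
  # multiplying back by the divisor reproduces the numerator on valid points
  recon <- rs$amplitude[rs$valid] * div$absorbance[rs$valid]
  expect_lt(max(abs(recon - s$absorbance[rs$valid])), 1e-9)
})

test_that("derivative kills constants, reproduces ramps, and is linear", {
  const <- new_spectrum(test_grid, rep(0.42, 751))
  d0 <- derivative_spectrum(const)
  expect_true(all(d0$amplitude[d0$valid] == 0))
  m <- 0.003
  ramp <- new_spectrum(test_grid, m * (test_grid - 200))
  d1 <- derivative_spectrum(ramp, deriv_config(delta_lambda = 4, scale = 10))
  for (w in c(230, 275.5, 320)) {
    expect_equal(value_at(d1, w), m * 10, tolerance = 1e-9)
  }
  # edges masked to half a window
  expect_false(any(d1$valid[1:10]))
  expect_false(any(d1$valid[742:751]))
  # linearity: D(2f + 3g) = 2 D(f) + 3 D(g)
  f <- basis_spectrum(test_models$asp, test_grid)
  g <- basis_spectrum(test_models$rox, test_grid)
  comb <- new_spectrum(test_grid, 2 * f$absorbance + 3 * g$absorbance)
  dc <- derivative_spectrum(comb)
  df <- derivative_spectrum(f)
  dg <- derivative_spectrum(g)
  ok <- dc$valid
  expect_lt(max(abs(dc$amplitude[ok] - 2 * df$amplitude[ok] - 3 * dg$amplitude[ok])),
            1e-9)
  # symmetric Gaussian: derivative crosses zero at the peak center
  peak <- new_spectrum(test_grid, exp(-(test_grid - 270)^2 / 200))
  dp <- derivative_spectrum(peak)
  expect_equal(value_at(dp, 270), 0, tolerance = 1e-12)
  expect_gt(value_at(dp, 265), 0)
  expect_lt(value_at(dp, 275), 0)
  # a window not representable on the grid is rejected
  expect_error(derivative_spectrum(ramp, deriv_config(delta_lambda = 0.5)),
               "multiple")
  expect_error(derivative_spectrum(ramp, deriv_config(delta_lambda = 0.2)),
               "even")
})

test_that("Savitzky-Golay derivative agrees with the ramp slope", {
  skip_if_not_installed("signal")
  m <- -0.002
  ramp <- new_spectrum(test_grid, m * (test_grid - 350))
  d <- derivative_spectrum(ramp, deriv_config(method = "savgol"))
  expect_equal(value_at(d, 275), m * 10, tolerance = 1e-9)
})

test_that("invalid ratio points poison the derivative stencil", {
  s <- make_mixture(test_models, c(rox = 10))
  rs <- ratio_spectrum(s, test_divisor("rox"))
  d <- derivative_spectrum(rs)
  edge <- max(which(rs$valid))
  expect_false(d$valid[[edge]]) # last valid ratio point has no right neighbour
  expect_error(value_at(d, rs$wavelength[[edge]]), "masked")
})

test_that("value_at reads nodes exactly, interpolates midpoints, guards range", {
  s <- new_spectrum(scan_grid(200, 201, 0.2), c(0.2, 0.4, 0.1, 0.3, 0.5, 0.6))
  expect_identical(value_at(s, 200.4), 0.1)
  expect_equal(value_at(s, 200.1), 0.3, tolerance = 1e-12)
  expect_error(value_at(s, 199), "outside")
  expect_error(value_at(s, 201.4), "outside")
})
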
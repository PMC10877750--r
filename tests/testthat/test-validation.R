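test_that("fit_line matches hand OLS and the normal equations", {
  f <- fit_line(c(1, 2, 3), c(3, 5, 7)) # y = 2x + 1
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  expect_equal(f$residual_sd, 0, tolerance = 1e-12)
  # hand OLS: slope = 3/2, intercept = mean(y) - slope * mean(x) = -2/3
  f2 <- fit_line(c(1, 2, 3), c(1, 2, 4))
  expect_equal(f2$slope, 1.5, tolerance = 1e-12)
  expect_equal(f2$intercept, -2 / 3, tolerance = 1e-12)
  # permutation invariance
  f3 <- fit_line(c(3, 1, 2), c(4, 1, 2))
  expect_equal(f3$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f3$intercept, f2$intercept, tolerance = 1e-12)
  # closed-form normal equations as an independent oracle
  set.seed(11)
  x <- runif(9, 1, 40)
  y <- 0.02 * x + 0.05 + rnorm(9, 0, 0.01)
  f4 <- fit_line(x, y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(f4$slope, b, tolerance = 1e-10)
  expect_equal(f4$intercept, a, tolerance = 1e-10)
  expect_equal(f4$residual_sd, sqrt(sum((y - a - b * x)^2) / 7),
               tolerance = 1e-10)
  expect_error(fit_line(c(1, 1, 1), c(1, 2, 3)), "equal")
})

test_that("tidy and glance expose the calibration in broom shape", {
  cal <- dw_calibrate(test_standards("asp"), c(231.6, 251.6), analyte = "asp")
  td <- tidy(cal)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(cal)
  expect_equal(gl$method, "dw")
  expect_equal(gl$n, 6)
  expect_equal(gl$slope, cal$slope)
})

test_that("recovery and precision follow their definitions", {
  expect_equal(recovery_percent(10, 10), 100)
  expect_equal(recovery_percent(9.9, 10), 99)
  expect_equal(recovery_percent(4.04, 4), 101)
  expect_error(recovery_percent(1, 0), "> 0")
  expect_equal(precision_rsd(c(5, 5, 5)), 0)
  expect_equal(precision_rsd(c(99, 100, 101)), 1, tolerance = 1e-12)
  expect_equal(precision_rsd(3 * c(99, 100, 101)), 1, tolerance = 1e-12)
  expect_error(precision_rsd(c(-1, 1)), "zero")
})

test_that("detection limits follow the 3.3/10 sigma-over-slope rule", {
  fit <- list(slope = 0.5, residual_sd = 0.05, se_intercept = 0.02)
  lims <- lod_loq(fit)
  expect_equal(lims$lod, 0.33, tolerance = 1e-12)
  expect_equal(lims$loq, 1.0, tolerance = 1e-12)
  lims2 <- lod_loq(fit, sigma_source = "intercept_sd")
  expect_equal(lims2$lod, 3.3 * 0.02 / 0.5, tolerance = 1e-12)
  # the LOQ/LOD ratio is forced for any input
  set.seed(21)
  for (i in 1:20) {
    f <- list(slope = runif(1, -2, 2), residual_sd = runif(1, 1e-4, 1))
    if (abs(f$slope) < 1e-3) next
    l <- lod_loq(f)
    expect_equal(l$loq / l$lod, 10 / 3.3, tolerance = 1e-12)
  }
  exact <- fit_line(c(1, 2, 3), c(3, 5, 7))
  l0 <- lod_loq(exact)
  expect_equal(unlist(l0), c(lod = 0, loq = 0), tolerance = 1e-12)
})

test_that("standard addition extrapolates to the x-intercept", {
  expect_equal(standard_addition(1, c(1, 2), c(2, 3)), 1, tolerance = 1e-12)
  expect_equal(standard_addition(0, c(1, 2), c(1, 2)), 0, tolerance = 1e-12)
  # doubling all signals leaves the estimate unchanged
  expect_equal(standard_addition(2, c(1, 2), c(4, 6)),
               standard_addition(1, c(1, 2), c(2, 3)), tolerance = 1e-12)
  expect_error(standard_addition(3, c(1, 2), c(2, 1)), "positive")
})

test_that("pooled t and F match hand computation on textbook cases", {
  expect_equal(pooled_t(summary_stats(10, 1, 5), summary_stats(10, 1, 5))$t, 0)
  tt <- pooled_t(summary_stats(10, 1, 5), summary_stats(12, 1, 5))
  expect_equal(tt$t, sqrt(10), tolerance = 1e-9) # 3.16228
  expect_equal(tt$df, 8)
  ff <- f_test(summary_stats(100, 2, 5), summary_stats(100, 1, 5))
  expect_equal(ff$F, 4)
  expect_equal(f_test(summary_stats(1, 1, 5), summary_stats(2, 1, 8))$F, 1)
  expect_error(f_test(summary_stats(1, 0, 5), summary_stats(1, 1, 5)), "> 0")
})

test_that("summary-statistic t and F agree with a raw-data oracle", {
  # raw samples affine-standardized to exact mean/sd, textbook tests as oracle
  make_raw <- function(m, s, n, seed) {
    z <- withr::with_seed(seed, stats::rnorm(n))
    z <- (z - mean(z)) / stats::sd(z)
    m + s * z
  }
  cases <- list(c(100.2, 0.9, 8, 100.6, 1.2, 6),
                c(99.5, 0.4, 10, 100.1, 0.5, 10),
                c(50, 2, 5, 55, 1, 12))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    x <- make_raw(cs[1], cs[2], cs[3], seed = 100 + k)
    y <- make_raw(cs[4], cs[5], cs[6], seed = 200 + k)
    a <- summary_stats(cs[1], cs[2], cs[3])
    b <- summary_stats(cs[4], cs[5], cs[6])
    tt <- pooled_t(a, b)
    oracle_t <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(tt$t, abs(unname(oracle_t$statistic)), tolerance = 1e-10)
    expect_equal(tt$df, unname(oracle_t$parameter))
    ff <- f_test(a, b)
    oracle_f <- stats::var.test(x, y)
    expect_equal(ff$F, max(oracle_f$estimate, 1 / oracle_f$estimate),
                 tolerance = 1e-10)
  }
})

test_that("fitted slopes recover the generating slope at nominal coverage", {
  # 200 seeded noisy calibrations, n = 7 levels, 1% relative noise:
  # the true slope must lie within 3 SE of the fit in at least 95% of runs
  true_slope <- 0.025
  levels <- c(4, 10, 16, 22, 28, 34, 40)
  hits <- withr::with_seed(31, {
    purrr::map_lgl(1:200, function(i) {
      y <- true_slope * levels * (1 + stats::rnorm(7, 0, 0.01))
      f <- fit_line(levels, y)
      abs(f$slope - true_slope) <= 3 * f$se_slope
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("method comparison reproduces pass/fail against the comparator", {
  out <- compare_methods(reference_assay_stats())
  expect_equal(nrow(out), 6)
  expect_false(any(out$t_significant))
  expect_false(any(out$F_significant))
})
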
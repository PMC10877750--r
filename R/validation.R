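#' Recovery percentage
#'
#' `100 * found / true`, the accuracy measure of an assay determination.
#'
#' @param found Found concentration(s), ug/mL.
#' @param true True concentration(s), > 0.
#' @return Recovery in percent.
#' @examples
#' recovery_percent(9.9, 10) # 99
#' @export
recovery_percent <- function(found, true) {
  if (any(true <= 0)) rlang::abort("True concentrations must be > 0.")
  100 * found / true
}

#' Relative standard deviation (precision)
#'
#' `100 * sd / mean` over replicate determinations; reported for
#' repeatability (intra-day) and intermediate precision (inter-day).
#'
#' @param values Numeric vector, >= 2 values, nonzero mean.
#' @return RSD in percent.
#' @examples
#' precision_rsd(c(99, 100, 101)) # 1
#' @export
precision_rsd <- function(values) {
  if (length(values) < 2) rlang::abort("Need >= 2 values.")
  m <- mean(values)
  if (m == 0) rlang::abort("Mean of values is zero.")
  100 * stats::sd(values) / m
}

#' Detection and quantitation limits
#'
#' ICH-style limits from a calibration line: `LOD = 3.3 sigma / |slope|`,
#' `LOQ = 10 sigma / |slope|`, where sigma is either the residual SD of the
#' regression (default) or the standard error of its intercept. The
#' LOQ / LOD ratio is 10 / 3.3 by construction.
#'
#' @param fit A `linear_fit` or `uv_calibration`.
#' @param sigma_source `"residual_sd"` or `"intercept_sd"`.
#' @return One-row tibble: `lod`, `loq` (ug/mL).
#' @export
lod_loq <- function(fit, sigma_source = c("residual_sd", "intercept_sd")) {
  sigma_source <- rlang::arg_match(sigma_source)
  if (is.null(fit$slope) || fit$slope == 0) rlang::abort("Slope must be nonzero.")
  sigma <- switch(sigma_source, residual_sd = fit$residual_sd,
                  intercept_sd = fit$se_intercept)
  if (!is.finite(sigma)) rlang::abort("No usable sigma on this fit.")
  tibble::tibble(lod = 3.3 * sigma / abs(fit$slope),
                 loq = 10 * sigma / abs(fit$slope))
}

#' Standard addition estimate
#'
#' Regresses the signal on the added concentration, including the unspiked
#' base sample as the point at zero addition, and extrapolates to the
#' x-intercept: the original content is `intercept / slope`.
#'
#' @param base_response Signal of the unspiked sample.
#' @param added Added concentrations (ug/mL), >= 2 levels.
#' @param signal Signals at the added levels.
#' @return Estimated original concentration, ug/mL.
#' @examples
#' standard_addition(1, c(1, 2), c(2, 3)) # 1
#' @export
standard_addition <- function(base_response, added, signal) {
  if (length(added) < 2) rlang::abort("Need >= 2 addition levels.")
  fit <- fit_line(c(0, added), c(base_response, signal))
  if (fit$slope <= 0) rlang::abort("Standard-addition slope must be positive.")
  fit$intercept / fit$slope
}

#' Summary statistics of an assay series
#'
#' Container for the mean recovery, dispersion and size of one assay series,
#' the inputs of the between-method t and F comparisons. Either `sd` or
#' `variance` may be given; when both are, they must agree.
#'
#' When both are given they may disagree by up to 5% relative (published
#' tables round both independently); the supplied `variance` is what the
#' tests use. Larger disagreement is an error.
#'
#' @param mean Mean recovery, %.
#' @param sd Standard deviation, % (optional if `variance` given).
#' @param n Number of determinations (>= 2).
#' @param variance Variance, %^2 (optional if `sd` given).
#' @return A one-row `summary_stats` tibble: `mean`, `sd`, `n`, `variance`.
#' @export
summary_stats <- function(mean, sd = NULL, n, variance = NULL) {
  if (n < 2) rlang::abort("`n` must be >= 2.")
  if (is.null(sd) && is.null(variance)) rlang::abort("Give `sd` or `variance`.")
  if (is.null(sd)) sd <- sqrt(variance)
  if (is.null(variance)) variance <- sd^2
  if (sd < 0) rlang::abort("`sd` must be >= 0.")
  if (abs(variance - sd^2) > 0.05 * max(variance, sd^2)) {
    rlang::abort("`sd` and `variance` are inconsistent.")
  }
  out <- tibble::tibble(mean = mean, sd = sd, n = as.integer(n),
                        variance = variance)
  class(out) <- c("summary_stats", class(out))
  out
}

as_summary <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.data.frame(x)) {
    summary_stats(mean = x$mean[[1]],
                  sd = if ("sd" %in% names(x)) x$sd[[1]] else NULL,
                  n = x$n[[1]],
                  variance = if ("variance" %in% names(x)) x$variance[[1]] else NULL)
  } else {
    summary_stats(mean = x$mean, sd = x$sd %||% NULL, n = x$n,
                  variance = x$variance %||% NULL)
  }
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance (pooled) two-sample t statistic:
#' `sp^2 = ((n1-1) v1 + (n2-1) v2) / (n1+n2-2)`,
#' `t = |m1 - m2| / (sp sqrt(1/n1 + 1/n2))`, df = `n1 + n2 - 2`, compared to
#' the two-tailed 5% critical value. The pooled form (not Welch) matches the
#' degrees of freedom conventionally reported for assay comparisons.
#'
#' @param a,b `summary_stats` (or anything with mean, sd/variance, n).
#' @return One-row tibble: `t`, `df`, `t_crit`, `significant`.
#' @examples
#' pooled_t(summary_stats(10, 1, 5), summary_stats(12, 1, 5)) # t = 3.1623
#' @export
pooled_t <- function(a, b) {
  a <- as_summary(a); b <- as_summary(b)
  df <- a$n + b$n - 2
  if (df < 1) rlang::abort("Need n1 + n2 > 2.")
  sp2 <- ((a$n - 1) * a$variance + (b$n - 1) * b$variance) / df
  t <- abs(a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  t_crit <- stats::qt(0.975, df)
  tibble::tibble(t = t, df = df, t_crit = t_crit, significant = t > t_crit)
}

#' Variance-ratio F test from summary statistics
#'
#' `F = larger variance / smaller variance` (so F >= 1), with the matching
#' (n - 1) degrees of freedom, compared to the upper 5% critical value.
#'
#' @param a,b `summary_stats` (or anything with mean, sd/variance, n).
#' @return One-row tibble: `F`, `df_num`, `df_den`, `F_crit`, `significant`.
#' @examples
#' f_test(summary_stats(100, 2, 5), summary_stats(100, 1, 5)) # F = 4
#' @export
f_test <- function(a, b) {
  a <- as_summary(a); b <- as_summary(b)
  if (a$variance <= 0 || b$variance <= 0) rlang::abort("Variances must be > 0.")
  if (a$variance >= b$variance) {
    num <- a; den <- b
  } else {
    num <- b; den <- a
  }
  f <- num$variance / den$variance
  f_crit <- stats::qf(0.95, num$n - 1, den$n - 1)
  tibble::tibble(F = f, df_num = num$n - 1L, df_den = den$n - 1L,
                 F_crit = f_crit, significant = f > f_crit)
}

#' Reported mean recoveries of the published determinations
#'
#' Mean recovery (%), SD, n and variance of the published pure-powder
#' determinations of the aspirin-like (ASP) and rivaroxaban-like (ROX)
#' analytes by the three spectrophotometric methods, together with the
#' comparator assays (the official titrimetric method for ASP, the reported
#' HPLC method for ROX). Shipped as reference constants: they drive the
#' between-method t/F comparison examples and are not recomputed.
#'
#' @return Tibble: `analyte`, `method`, `mean`, `sd`, `n`, `variance`.
#' @export
reference_assay_stats <- function() {
  tibble::tribble(
    ~analyte, ~method, ~mean, ~sd, ~n, ~variance,
    "ASP", "dw", 100.26, 1.00, 10L, 1.00,
    "ASP", "rd", 100.11, 1.05, 10L, 1.11,
    "ASP", "dd", 99.70, 0.89, 10L, 0.79,
    "ASP", "comparator", 100.22, 0.95, 6L, 0.90,
    "ROX", "dw", 100.06, 0.97, 8L, 0.94,
    "ROX", "rd", 100.24, 0.68, 8L, 0.47,
    "ROX", "dd", 99.67, 0.706, 8L, 0.49,
    "ROX", "comparator", 100.48, 0.92, 6L, 0.84
  )
}

#' Compare assay methods against a comparator from summary statistics
#'
#' Runs [pooled_t()] and [f_test()] of every method row against the
#' comparator row, per analyte. Input rows need `analyte`, `method`, `mean`,
#' `n` and `sd` and/or `variance`; the comparator is the row whose `method`
#' equals `comparator`.
#'
#' @param stats_tbl Tibble of summary rows, e.g. [reference_assay_stats()].
#' @param comparator Method label of the reference assay.
#' @return Tibble: analyte, method, t, df, t_crit, t_significant, F, df_num,
#'   df_den, F_crit, F_significant.
#' @export
compare_methods <- function(stats_tbl, comparator = "comparator") {
  if (!all(c("analyte", "method", "mean", "n") %in% names(stats_tbl))) {
    rlang::abort("Need columns analyte, method, mean, n (+ sd or variance).")
  }
  purrr::map_dfr(unique(stats_tbl$analyte), function(an) {
    sub <- dplyr::filter(stats_tbl, .data$analyte == an)
    ref <- dplyr::filter(sub, .data$method == comparator)
    if (nrow(ref) != 1) rlang::abort(sprintf("No single comparator row for %s.", an))
    others <- dplyr::filter(sub, .data$method != comparator)
    purrr::map_dfr(seq_len(nrow(others)), function(i) {
      tt <- pooled_t(others[i, ], ref)
      ff <- f_test(others[i, ], ref)
      tibble::tibble(
        analyte = an, method = others$method[[i]],
        t = tt$t, df = tt$df, t_crit = tt$t_crit, t_significant = tt$significant,
        F = ff$F, df_num = ff$df_num, df_den = ff$df_den, F_crit = ff$F_crit,
        F_significant = ff$significant
      )
    })
  })
}

#' Validation report for predicted vs true concentrations
#'
#' Per analyte/method/level: mean recovery, SD and RSD over replicates; plus
#' a per-method grand mean. Mirrors the usual accuracy/precision summary of
#' an assay validation.
#'
#' @param predictions Tibble with columns `analyte`, `method`, `true`,
#'   `found` (one row per replicate determination).
#' @return List of two tibbles: `by_level` and `by_method`.
#' @export
validation_report <- function(predictions) {
  predictions <- dplyr::mutate(predictions,
                               recovery = recovery_percent(.data$found, .data$true))
  by_level <- predictions |>
    dplyr::group_by(.data$analyte, .data$method, .data$true) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_recovery = mean(.data$recovery),
      sd_recovery = stats::sd(.data$recovery),
      rsd = ifelse(dplyr::n() > 1, precision_rsd(.data$recovery), NA_real_),
      .groups = "drop"
    )
  by_method <- predictions |>
    dplyr::group_by(.data$analyte, .data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_recovery = mean(.data$recovery),
      sd_recovery = stats::sd(.data$recovery),
      .groups = "drop"
    )
  list(by_level = by_level, by_method = by_method)
}
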